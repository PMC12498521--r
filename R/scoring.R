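#' Sequence prediction score and probability
#'
#' The sequence prediction score (SPS) of a taxon is its linear predictor
#' `x . beta + intercept`; the sequence prediction probability (SPP) is the
#' logistic transform of the SPS, i.e. the predicted probability of the +1
#' class. SPS >= 0 (equivalently SPP >= 0.5) classifies the taxon into the
#' focal (+1) class.
#'
#' @param model An `esl_model`.
#' @param row A single encoded row (numeric vector over the model's bit
#'   columns).
#' @return List with `sps`, `spp` and `class` (+1 or -1).
#' @export
sequence_prediction <- function(model, row) {
  stopifnot(length(row) == length(model$beta))
  sps <- sum(row * model$beta) + model$intercept
  list(sps = sps, spp = stats::plogis(sps), class = if (sps >= 0) 1 else -1)
}

#' SPS for every row of an encoded matrix
#'
#' @param model An `esl_model`.
#' @param X Encoded rows (taxa x bit columns).
#' @return Named numeric vector of SPS values.
#' @export
predict_sps <- function(model, X) {
  stopifnot(ncol(X) == length(model$beta))
  stats::setNames(as.numeric(X %*% model$beta) + model$intercept,
                  rownames(X))
}

#' Position sparsity scores
#'
#' The PSS of an alignment position is the sum of |beta| over that
#' position's bit columns; positions whose columns are all zero score 0.
#'
#' @param model An `esl_model` carrying a feature map.
#' @return data.frame with `group`, `position`, `pss`, one row per encoded
#'   position, in feature-map order.
#' @export
position_scores <- function(model) {
  fm <- model$feature_map
  if (is.null(fm)) stop("model has no feature map", call. = FALSE)
  key <- paste(fm$group, fm$position, sep = "\r")
  agg <- rowsum(abs(model$beta), key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(group = vapply(parts, `[`, character(1), 1L),
             position = as.integer(vapply(parts, `[`, character(1), 2L)),
             pss = as.numeric(agg),
             stringsAsFactors = FALSE)
}

#' Group sparsity scores
#'
#' GSS of a group = sum of PSS over its positions, so group scores add up
#' exactly to the hypothesis score.
#'
#' @param pss Output of [position_scores()].
#' @param groups An `esl_groups` structure (fixes group order; groups with
#'   no surviving positions score 0).
#' @return data.frame with `group` and `gss`.
#' @export
group_scores <- function(pss, groups) {
  sums <- rowsum(pss$pss, pss$group, reorder = FALSE)
  gss <- stats::setNames(rep(0, nrow(groups)), groups$name)
  gss[rownames(sums)] <- as.numeric(sums)
  data.frame(group = groups$name, gss = as.numeric(gss),
             stringsAsFactors = FALSE)
}

#' Hypothesis sparsity score
#'
#' @param gss Output of [group_scores()].
#' @return Sum of the group scores (the intercept is excluded).
#' @export
hypothesis_score <- function(gss) sum(gss$gss)

#' All sparsity and prediction scores of a model
#'
#' @param model An `esl_model` with a feature map.
#' @param X Encoded rows of the taxa to score (training matrix, typically).
#' @param normalize Divide PSS and GSS by the hypothesis score (when it is
#'   positive) so scores are comparable across models.
#' @return An `esl_scores` list: `sps`, `spp` (named by taxon), `pss`,
#'   `gss`, `hss`.
#' @export
score_tables <- function(model, X, normalize = FALSE) {
  sps <- predict_sps(model, X)
  pss <- position_scores(model)
  gss <- group_scores(pss, model$groups)
  hss <- hypothesis_score(gss)
  if (normalize && hss > 0) {
    pss$pss <- pss$pss / hss
    gss$gss <- gss$gss / hss
  }
  structure(list(sps = sps, spp = stats::plogis(sps), pss = pss, gss = gss,
                 hss = hss),
            class = "esl_scores")
}

# lambda value encoded for file names: "2" for 0.2, "025" for 0.25
.lambda_code <- function(lambda) {
  x <- lambda * 10
  if (abs(x - round(x)) < 1e-9) {
    as.character(round(x))
  } else {
    gsub(".", "", format(lambda, scientific = FALSE), fixed = TRUE)
  }
}

.num <- function(x) sprintf("%.17g", x)

#' Write a fitted model to a tab-separated text file
#'
#' Only bit columns with nonzero coefficients are listed (they are the
#' model). Header lines record the intercept, both lambdas, the hypothesis
#' name and the data type, so the file is self-contained for later
#' classification of new sequences. The file name follows the
#' `MyESL_model_<hypothesis>_<lambda1 x 10>_<lambda2 x 10>.txt` convention
#' of the wider ESL tool family. Numbers are written with full double
#' precision so a write/read round trip reproduces predictions exactly.
#'
#' @param model An `esl_model` with a feature map.
#' @param out_dir Output directory (created if needed).
#' @param data_type Data-type mode recorded in the header.
#' @return The path of the written file, invisibly.
#' @export
write_model <- function(model, out_dir, data_type = "nucleotide") {
  fm <- model$feature_map
  if (is.null(fm)) stop("model has no feature map", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fname <- paste0("MyESL_model_", model$hypothesis_name, "_",
                  .lambda_code(model$lambda1), "_",
                  .lambda_code(model$lambda2), ".txt")
  path <- file.path(out_dir, fname)
  nz <- which(model$beta != 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#hypothesis\t", model$hypothesis_name),
               paste0("#data_type\t", data_type),
               paste0("#lambda1\t", .num(model$lambda1)),
               paste0("#lambda2\t", .num(model$lambda2)),
               paste0("#intercept\t", .num(model$intercept)),
               "bit_column\tgroup\tposition\tchar\tbeta"), con)
  if (length(nz)) {
    writeLines(paste(bit_column_names(fm)[nz], fm$group[nz], fm$position[nz],
                     fm$char[nz], .num(model$beta[nz]), sep = "\t"), con)
  }
  invisible(path)
}

#' Read a model file back into an `esl_model`
#'
#' When a feature map is supplied (the training encoding), coefficients are
#' placed at the matching bit columns and every other column gets beta = 0;
#' a model column absent from the feature map is an error. Without a feature
#' map, the model's own columns define the feature map (sufficient for
#' classifying new sequences, since absent columns contribute nothing).
#'
#' @param path Path to a file written by [write_model()].
#' @param feature_map Optional training feature map.
#' @return An `esl_model` (with `data_type` attribute).
#' @export
read_model <- function(path, feature_map = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  hkv <- strsplit(hdr, "\t", fixed = TRUE)
  hmap <- stats::setNames(vapply(hkv, `[`, character(1), 2L),
                          sub("^#", "", vapply(hkv, `[`, character(1), 1L)))
  body <- body[nzchar(body)]
  tab <- if (length(body) > 1L) {
    utils::read.table(text = body, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "integer",
                                     "character", "numeric"))
  } else {
    data.frame(bit_column = character(0), group = character(0),
               position = integer(0), char = character(0),
               beta = numeric(0))
  }
  if (is.null(feature_map)) {
    feature_map <- data.frame(bit_index = seq_len(nrow(tab)) - 1L,
                              group = tab$group, position = tab$position,
                              char = tab$char, stringsAsFactors = FALSE)
    beta <- tab$beta
  } else {
    idx <- match(tab$bit_column, bit_column_names(feature_map))
    if (anyNA(idx)) {
      stop("model column(s) not present in feature map: ",
           paste(tab$bit_column[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    beta <- numeric(nrow(feature_map))
    beta[idx] <- tab$beta
  }
  model <- structure(
    list(beta = beta, intercept = as.numeric(hmap[["intercept"]]),
         lambda1 = as.numeric(hmap[["lambda1"]]),
         lambda2 = as.numeric(hmap[["lambda2"]]),
         groups = group_structure(feature_map),
         feature_map = feature_map,
         hypothesis_name = unname(hmap[["hypothesis"]])),
    class = "esl_model")
  attr(model, "data_type") <- unname(hmap[["data_type"]])
  model
}

#' Write requested sparsity/prediction score files
#'
#' One tab-separated file per requested letter: `P` position scores, `G`
#' group scores, `H` the hypothesis score, `S` a single file with both SPS
#' and SPP per taxon.
#'
#' @param tables An `esl_scores` object.
#' @param which String of letters from `PGHS`.
#' @param out_dir Output directory.
#' @param prefix File-name prefix (typically the hypothesis name).
#' @return Named character vector of written paths, invisibly.
#' @export
write_stats <- function(tables, which, out_dir, prefix = "model") {
  letters_req <- unique(strsplit(which, "")[[1]])
  bad <- setdiff(letters_req, c("P", "G", "H", "S"))
  if (length(bad)) {
    stop("unknown stats code '", paste(bad, collapse = ""),
         "' (valid letters: P, G, H, S)", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  fmt <- function(x) sprintf("%.10g", x)
  if ("P" %in% letters_req) {
    p <- file.path(out_dir, paste0(prefix, "_PSS.txt"))
    utils::write.table(
      data.frame(group = tables$pss$group, position = tables$pss$position,
                 PSS = fmt(tables$pss$pss)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["P"] <- p
  }
  if ("G" %in% letters_req) {
    p <- file.path(out_dir, paste0(prefix, "_GSS.txt"))
    utils::write.table(
      data.frame(group = tables$gss$group, GSS = fmt(tables$gss$gss)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["G"] <- p
  }
  if ("H" %in% letters_req) {
    p <- file.path(out_dir, paste0(prefix, "_HSS.txt"))
    utils::write.table(
      data.frame(hypothesis = prefix, HSS = fmt(tables$hss)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["H"] <- p
  }
  if ("S" %in% letters_req) {
    p <- file.path(out_dir, paste0(prefix, "_SPS_SPP.txt"))
    utils::write.table(
      data.frame(taxon = names(tables$sps), SPS = fmt(tables$sps),
                 SPP = fmt(tables$spp)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["S"] <- p
  }
  invisible(paths)
}

#' Per-taxon, per-group model contribution grid
#'
#' For each taxon and group, the sum of `x . beta` restricted to the
#' group's bit columns: a text rendering of the model grid showing which
#' loci pull each taxon towards or away from the focal class.
#'
#' @param model An `esl_model`.
#' @param X Encoded rows.
#' @return Numeric matrix (taxa x groups).
#' @export
contribution_grid <- function(model, X) {
  grid <- vapply(seq_len(nrow(model$groups)), function(g) {
    idx <- (model$groups$start[g] + 1L):model$groups$end[g]
    as.numeric(X[, idx, drop = FALSE] %*% model$beta[idx])
  }, numeric(nrow(X)))
  grid <- matrix(grid, nrow = nrow(X),
                 dimnames = list(rownames(X), model$groups$name))
  grid
}

#' Write the contribution grid as a TSV
#'
#' @param model An `esl_model`.
#' @param X Encoded rows.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_contribution_grid <- function(model, X, path) {
  grid <- contribution_grid(model, X)
  txt <- grid
  txt[] <- sprintf("%.10g", grid)
  df <- data.frame(taxon = rownames(grid), as.data.frame(txt),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
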