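#' Encode new taxa against a trained model's feature map
#'
#' New sequences must already be aligned with the training data: positions
#' correspond by index, which is checked by requiring each group's
#' alignment to be at least as long as the largest position the model uses.
#' For each model bit column (group, position, character), a taxon scores 1
#' when it carries exactly that character there and 0 otherwise; gaps,
#' missing data and characters unseen in training contribute 0.
#'
#' @param aln An `esl_alignment_set` containing the new taxa.
#' @param feature_map Feature map of the model's bit columns.
#' @param taxa Taxa to encode (e.g. from a new-species list file).
#' @param policy Data-type policy used in training (fixes case folding).
#' @return Binary matrix (taxa x model bit columns).
#' @export
encode_against_model <- function(aln, feature_map, taxa,
                                 policy = data_type_policy("nucleotide")) {
  if (!length(taxa)) stop("empty taxa list", call. = FALSE)
  absent <- setdiff(taxa, aln$taxa)
  if (length(absent)) {
    stop("taxa not found in alignments: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  for (g in unique(feature_map$group)) {
    if (!g %in% names(aln$groups)) {
      stop("alignment group '", g, "' required by the model is missing",
           call. = FALSE)
    }
    need <- max(feature_map$position[feature_map$group == g])
    have <- ncol(aln$groups[[g]])
    if (have < need) {
      stop("alignment for group '", g, "' has ", have,
           " positions but the model references position ", need,
           "; sequences must be aligned with the training data",
           call. = FALSE)
    }
  }
  X <- matrix(0, nrow = length(taxa), ncol = nrow(feature_map),
              dimnames = list(taxa, bit_column_names(feature_map)))
  for (j in seq_len(nrow(feature_map))) {
    chars <- aln$groups[[feature_map$group[j]]][taxa, feature_map$position[j]]
    states <- .policy_states(chars, policy)
    X[, j] <- as.numeric(!is.na(states) & states == feature_map$char[j])
  }
  X
}

#' Classify new taxa with a pretrained model
#'
#' @param model An `esl_model` (typically from [read_model()]).
#' @param rows Encoded rows from [encode_against_model()].
#' @param out_dir Optional output directory; when given, a tab-separated
#'   prediction table and the per-group contribution grid are written.
#' @return data.frame with `taxon`, `SPS`, `SPP` and `class` (+1 iff
#'   SPS >= 0).
#' @export
apply_model <- function(model, rows, out_dir = NULL) {
  if (!nrow(rows)) stop("empty taxa list", call. = FALSE)
  sps <- predict_sps(model, rows)
  out <- data.frame(taxon = rownames(rows), SPS = sps,
                    SPP = stats::plogis(sps),
                    class = ifelse(sps >= 0, 1L, -1L),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- out
    tab$SPS <- sprintf("%.10g", tab$SPS)
    tab$SPP <- sprintf("%.10g", tab$SPP)
    utils::write.table(tab,
                       file.path(out_dir,
                                 paste0(model$hypothesis_name,
                                        "_predictions.txt")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_contribution_grid(model, rows,
                            file.path(out_dir,
                                      paste0(model$hypothesis_name,
                                             "_grid.txt")))
  }
  out
}

#' Read a new-species list (one taxon name per line)
#'
#' @param path Path to the list file.
#' @return Character vector of taxa.
#' @export
read_species_list <- function(path) {
  if (!file.exists(path)) stop("species list file not found: ", path,
                               call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("species list ", path, " is empty", call. = FALSE)
  lines
}
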