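#' Character validity policy for a sequence data type
#'
#' Defines which characters count as valid states when one-hot encoding an
#' alignment. `nucleotide` accepts A, T, C, G and U (case-insensitive);
#' `protein` accepts the 20 unambiguous IUPAC amino-acid letters
#' (case-insensitive); `molecular` is their union; `universal` accepts all
#' letters (case-sensitive) and digits, for encoding arbitrary discrete
#' characters such as gene presence/absence or methylation states. The
#' alignment gap `-` and missing-data `?` characters are never valid states,
#' and any character outside the policy's set is treated as missing.
#'
#' @param mode One of `"nucleotide"`, `"protein"`, `"molecular"`,
#'   `"universal"`.
#' @return An object of class `esl_policy` with fields `mode`, `valid_chars`,
#'   `case_sensitive` and `missing_chars`.
#' @export
#' @examples
#' data_type_policy("nucleotide")$valid_chars
data_type_policy <- function(mode = c("nucleotide", "protein", "molecular",
                                      "universal")) {
  mode <- match.arg(mode)
  nuc <- c("A", "T", "C", "G", "U")
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  valid <- switch(mode,
    nucleotide = nuc,
    protein    = aa,
    molecular  = sort(union(nuc, aa)),
    universal  = c(LETTERS, letters, as.character(0:9)))
  structure(
    list(mode = mode, valid_chars = valid,
         case_sensitive = identical(mode, "universal"),
         missing_chars = c("-", "?")),
    class = "esl_policy")
}

#' Read a list of alignment file paths
#'
#' The primary sequence input is a plain-text file naming one FASTA alignment
#' per line. Blank lines and surrounding whitespace are ignored. Entries that
#' are not found as given are also tried relative to the directory of the
#' list file, so a list can sit next to its alignments.
#'
#' @param path Path to the list file.
#' @return Character vector of FASTA paths, in file order.
#' @export
read_alignment_list <- function(path) {
  if (!file.exists(path)) {
    stop("alignment list file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  vapply(lines, function(ln) {
    if (file.exists(ln)) return(ln)
    alt <- file.path(dirname(path), ln)
    if (file.exists(alt)) return(alt)
    stop("alignment file listed in ", path, " not found: ", ln, call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Load a set of FASTA alignments as one grouped alignment set
#'
#' Each FASTA file becomes one named group of alignment positions (typically
#' a gene or locus); the group name is the file basename without extension.
#' All files must contain exactly the same set of taxa; rows are normalized
#' to the taxon order of the first file so downstream matrices align. The
#' taxon name is the first whitespace-delimited token of the FASTA header.
#'
#' @param paths Character vector of FASTA paths (e.g. from
#'   [read_alignment_list()]).
#' @return An `esl_alignment_set`: list with `taxa` (canonical order) and
#'   `groups`, a named list of taxa-by-position character matrices.
#' @export
load_alignment_set <- function(paths) {
  if (!length(paths)) stop("no alignment files given", call. = FALSE)
  groups <- list()
  canonical <- NULL
  for (p in paths) {
    seqs <- Biostrings::readBStringSet(p)
    taxa <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
    if (anyDuplicated(taxa)) {
      stop("duplicate taxon '", taxa[anyDuplicated(taxa)], "' in ", p,
           call. = FALSE)
    }
    lens <- Biostrings::width(seqs)
    if (length(unique(lens)) != 1L) {
      stop("unequal sequence lengths in ", p,
           " (not an alignment): ", paste(unique(lens), collapse = ", "),
           call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(as.character(seqs), ""))
    rownames(mat) <- taxa
    if (is.null(canonical)) {
      canonical <- taxa
    } else if (!setequal(taxa, canonical)) {
      stop("taxon set in ", p, " differs from first alignment; ",
           "missing: ", paste(setdiff(canonical, taxa), collapse = ", "),
           "; extra: ", paste(setdiff(taxa, canonical), collapse = ", "),
           call. = FALSE)
    }
    gname <- sub("\\.[^.]*$", "", basename(p))
    groups[[gname]] <- mat[canonical, , drop = FALSE]
  }
  structure(list(taxa = canonical, groups = groups),
            class = "esl_alignment_set")
}

# fold case according to policy; invalid characters become NA (missing)
.policy_states <- function(chars, policy) {
  if (!policy$case_sensitive) chars <- toupper(chars)
  chars[!(chars %in% policy$valid_chars)] <- NA_character_
  chars
}

#' One-hot encode an alignment set into a binary design matrix
#'
#' Every alignment position contributes one bit column per distinct valid
#' character observed there (gaps, `?` and policy-invalid characters
#' contribute nothing). Three filters are then applied in order:
#' (1) positions monomorphic over the selected taxa are dropped (all valid
#' characters identical, ignoring missing; positions with no valid character
#' also fall here); (2) unless `include_singletons`, bit columns whose sum is
#' 1 are dropped; (3) bit columns with sum below `bit_ct` are dropped. The
#' surviving columns are described by the feature map, which ties each
#' 0-based bit index to its (group, 1-based position, character) triple,
#' ordered by group, position, then character lexicographically.
#'
#' @param aln An `esl_alignment_set`.
#' @param policy An `esl_policy` from [data_type_policy()].
#' @param include_singletons Keep bit columns carried by a single taxon.
#' @param bit_ct Minimum number of 1s a bit column must have to survive.
#' @param taxa_subset Optional character vector; encoding and all filters are
#'   computed over these taxa only (the taxa selected for analysis).
#' @return An `esl_encoded`: list with sparse binary `X` (taxa x bit
#'   columns), `taxa`, and `feature_map` (data.frame: `bit_index`, `group`,
#'   `position`, `char`).
#' @export
one_hot_encode <- function(aln, policy = data_type_policy("nucleotide"),
                           include_singletons = FALSE, bit_ct = 1L,
                           taxa_subset = NULL) {
  stopifnot(inherits(aln, "esl_alignment_set"), inherits(policy, "esl_policy"))
  if (bit_ct < 1L) stop("bit_ct must be >= 1", call. = FALSE)
  taxa <- if (is.null(taxa_subset)) aln$taxa else {
    missing <- setdiff(taxa_subset, aln$taxa)
    if (length(missing)) {
      stop("taxa not present in alignments: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    aln$taxa[aln$taxa %in% taxa_subset]
  }
  n <- length(taxa)
  cols <- list()   # each: list(group, position, char, rows)
  for (gname in names(aln$groups)) {
    mat <- aln$groups[[gname]][taxa, , drop = FALSE]
    for (pos in seq_len(ncol(mat))) {
      states <- .policy_states(mat[, pos], policy)
      obs <- sort(unique(states[!is.na(states)]))
      if (length(obs) < 2L) next             # monomorphic or all-missing
      for (ch in obs) {
        hits <- which(!is.na(states) & states == ch)
        s <- length(hits)
        if (!include_singletons && s == 1L) next
        if (s < bit_ct) next
        cols[[length(cols) + 1L]] <-
          list(group = gname, position = pos, char = ch, rows = hits)
      }
    }
  }
  if (!length(cols)) {
    stop("no informative features survive encoding filters", call. = FALSE)
  }
  i <- unlist(lapply(cols, `[[`, "rows"))
  j <- rep(seq_along(cols), vapply(cols, function(cc) length(cc$rows),
                                   integer(1)))
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, length(cols)),
                            dimnames = list(taxa, NULL))
  fm <- data.frame(
    bit_index = seq_along(cols) - 1L,
    group = vapply(cols, `[[`, character(1), "group"),
    position = vapply(cols, `[[`, integer(1), "position"),
    char = vapply(cols, `[[`, character(1), "char"),
    stringsAsFactors = FALSE)
  colnames(X) <- bit_column_names(fm)
  structure(list(X = X, taxa = taxa, feature_map = fm),
            class = "esl_encoded")
}

#' Canonical bit-column names
#'
#' @param feature_map A feature-map data.frame.
#' @return `"<group>:<position>:<char>"` for each row.
#' @export
bit_column_names <- function(feature_map) {
  paste(feature_map$group, feature_map$position, feature_map$char, sep = ":")
}

#' @export
print.esl_encoded <- function(x, ...) {
  cat("One-hot encoded alignment:", length(x$taxa), "taxa x",
      nrow(x$feature_map), "bit columns in",
      length(unique(x$feature_map$group)), "group(s)\n")
  invisible(x)
}
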