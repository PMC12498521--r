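# build a balanced-ish newick string over taxa by recursive halving
.balanced_newick <- function(taxa) {
  if (length(taxa) == 1L) return(taxa)
  half <- ceiling(length(taxa) / 2)
  paste0("(", .balanced_newick(taxa[seq_len(half)]), ",",
         .balanced_newick(taxa[-seq_len(half)]), ")")
}

#' Generate a synthetic alignment set with a planted clade signal
#'
#' Writes a complete, self-consistent test dataset: one FASTA alignment per
#' group, a rooted balanced tree whose first `n_taxa / 2` taxa form the
#' focal clade (internal label `CladeT`), a matching two-column class file,
#' an alignment list file and a clade-list file. Within each designated
#' informative group, the first `n_informative_sites` positions carry one
#' character state fixed inside the focal clade and a different state
#' outside (perfectly concordant with the hypothesis); every other cell is
#' drawn independently and uniformly from the alphabet, and a `missing_rate`
#' fraction of cells is replaced by the gap character. The generator uses
#' uniform noise with no substitution model or rate heterogeneity: it
#' exercises the learning machinery, not realistic sequence evolution.
#' Output is byte-deterministic for a given seed.
#'
#' @param out_dir Directory to write into (created if needed).
#' @param n_taxa Even number of taxa; the first half is the focal clade.
#' @param n_groups Number of alignment groups (FASTA files).
#' @param sites_per_group Alignment length of each group.
#' @param n_informative_sites Planted concordant positions per informative
#'   group.
#' @param informative_groups Indices of groups that carry the signal.
#' @param alphabet Character states (default nucleotides).
#' @param missing_rate Fraction of cells replaced by `-`.
#' @param seed Integer seed.
#' @return List with paths (`alignment_list`, `fasta`, `tree`, `classes`,
#'   `clade_list`), the `clade_label`, `focal_taxa`, and `truth` (data.frame
#'   of planted group/position pairs).
#' @export
make_planted_dataset <- function(out_dir, n_taxa = 20L, n_groups = 5L,
                                 sites_per_group = 50L,
                                 n_informative_sites = 2L,
                                 informative_groups = 1L,
                                 alphabet = c("A", "C", "G", "T"),
                                 missing_rate = 0, seed = 42L) {
  if (n_taxa %% 2L != 0L) stop("n_taxa must be even", call. = FALSE)
  if (n_informative_sites > sites_per_group) {
    stop("n_informative_sites exceeds sites_per_group", call. = FALSE)
  }
  if (any(informative_groups > n_groups)) {
    stop("informative_groups outside 1..n_groups", call. = FALSE)
  }
  if (length(alphabet) < 2L) stop("alphabet needs >= 2 states", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  focal <- taxa[seq_len(n_taxa / 2)]
  clade_label <- "CladeT"

  newick <- paste0("(", .balanced_newick(focal), clade_label, ",",
                   .balanced_newick(taxa[-seq_len(n_taxa / 2)]), ");")
  tree_path <- file.path(out_dir, "tree.nwk")
  writeLines(newick, tree_path)

  fasta_paths <- character(n_groups)
  truth <- data.frame(group = character(0), position = integer(0),
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    for (g in seq_len(n_groups)) {
      gname <- paste0("g", g)
      mat <- matrix(sample(alphabet, n_taxa * sites_per_group,
                           replace = TRUE),
                    nrow = n_taxa, dimnames = list(taxa, NULL))
      if (g %in% informative_groups && n_informative_sites > 0L) {
        for (s in seq_len(n_informative_sites)) {
          states <- sample(alphabet, 2)
          mat[focal, s] <- states[1]
          mat[setdiff(taxa, focal), s] <- states[2]
          truth <- rbind(truth,
                         data.frame(group = gname, position = s,
                                    stringsAsFactors = FALSE))
        }
      }
      if (missing_rate > 0) {
        mask <- matrix(stats::runif(length(mat)) < missing_rate,
                       nrow = n_taxa)
        mat[mask] <- "-"
      }
      fp <- file.path(out_dir, paste0(gname, ".fas"))
      writeLines(as.vector(rbind(paste0(">", taxa),
                                 apply(mat, 1, paste0, collapse = ""))),
                 fp)
      fasta_paths[g] <- fp
    }
  })

  list_path <- file.path(out_dir, "alignments.txt")
  writeLines(basename(fasta_paths), list_path)

  class_path <- file.path(out_dir, "classes.txt")
  writeLines(paste0(taxa, "\t", ifelse(taxa %in% focal, "+1", "-1")),
             class_path)

  clade_path <- file.path(out_dir, "clades.txt")
  writeLines(clade_label, clade_path)

  list(alignment_list = list_path, fasta = fasta_paths, tree = tree_path,
       classes = class_path, clade_list = clade_path,
       clade_label = clade_label, focal_taxa = focal, truth = truth)
}
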