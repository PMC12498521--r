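# write a FASTA alignment from a named character vector of sequences
write_fasta <- function(seqs, path) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

# alignment set built in memory from named sequence vectors (one per group)
make_aln <- function(..., dir = withr::local_tempdir(.local_envir = parent.frame())) {
  groups <- list(...)
  paths <- vapply(names(groups), function(g) {
    write_fasta(groups[[g]], file.path(dir, paste0(g, ".fas")))
  }, character(1))
  load_alignment_set(paths)
}

# single-column alignment set: one group, one position
column_aln <- function(chars, taxa = paste0("t", seq_along(chars))) {
  make_aln(g1 = stats::setNames(chars, taxa))
}

# brute-force re-derivation of the surviving feature map straight from the
# raw character matrices, applying the monomorphic/singleton/bit_ct rules
brute_force_feature_map <- function(aln, policy, include_singletons, bit_ct,
                                    taxa = aln$taxa) {
  out <- NULL
  for (g in names(aln$groups)) {
    mat <- aln$groups[[g]][taxa, , drop = FALSE]
    for (pos in seq_len(ncol(mat))) {
      ch <- mat[, pos]
      if (!policy$case_sensitive) ch <- toupper(ch)
      ch[!(ch %in% policy$valid_chars)] <- NA
      tab <- table(ch[!is.na(ch)])
      if (length(tab) < 2) next
      for (state in sort(names(tab))) {
        s <- tab[[state]]
        if (!include_singletons && s == 1) next
        if (s < bit_ct) next
        out <- rbind(out, data.frame(group = g, position = pos,
                                     char = state, count = s,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# random alignment with gaps and missing data
random_aln_files <- function(n_taxa, n_pos, dir, n_groups = 1,
                            alphabet = c("A", "C", "G", "T", "-", "?"),
                            probs = c(.22, .22, .22, .22, .06, .06)) {
  taxa <- sprintf("s%02d", seq_len(n_taxa))
  vapply(seq_len(n_groups), function(g) {
    seqs <- vapply(taxa, function(t) {
      paste0(sample(alphabet, n_pos, replace = TRUE, prob = probs),
             collapse = "")
    }, character(1))
    write_fasta(seqs, file.path(dir, paste0("rg", g, ".fas")))
  }, character(1))
}

# planted dataset shared across tests (built once per test run)
planted <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "eslkit-planted")
      ds <- make_planted_dataset(dir, n_taxa = 20L, n_groups = 5L,
                                 sites_per_group = 50L,
                                 n_informative_sites = 2L,
                                 informative_groups = 1L, seed = 42L)
      aln <- load_alignment_set(read_alignment_list(ds$alignment_list))
      enc <- one_hot_encode(aln, data_type_policy("nucleotide"))
      hyp <- read_class_file(ds$classes)
      cache <<- list(ds = ds, aln = aln, enc = enc, hyp = hyp,
                     y = unname(hyp$labels[enc$taxa]),
                     groups = group_structure(enc$feature_map))
    }
    cache
  }
})
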