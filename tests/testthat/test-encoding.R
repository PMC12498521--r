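test_that("alignment list parsing handles order, blanks and missing files", {
  dir <- withr::local_tempdir()
  write_fasta(c(a = "ACGT", b = "ACGA"), file.path(dir, "g1.fas"))
  write_fasta(c(a = "TT", b = "TA"), file.path(dir, "g2.fas"))
  lst <- file.path(dir, "alignments.txt")

  writeLines(c("g1.fas", "g2.fas"), lst)
  expect_equal(basename(read_alignment_list(lst)), c("g1.fas", "g2.fas"))

  writeLines(c("g1.fas", "", "  g2.fas  ", ""), lst)
  expect_equal(basename(read_alignment_list(lst)), c("g1.fas", "g2.fas"))

  writeLines(c("g1.fas", "missing.fas"), lst)
  expect_error(read_alignment_list(lst), "missing.fas")
  expect_error(read_alignment_list(file.path(dir, "nolist.txt")),
               "nolist.txt")
})

test_that("alignment sets load with canonical taxon order and strict checks", {
  aln <- make_aln(g1 = c(B = "ACGT", A = "ACGA", C = "TCGA"),
                  g2 = c(A = "TT", C = "TG", B = "GG"))
  expect_s3_class(aln, "esl_alignment_set")
  expect_equal(aln$taxa, c("B", "A", "C"))          # order of first file
  expect_equal(names(aln$groups), c("g1", "g2"))
  expect_equal(dim(aln$groups$g1), c(3L, 4L))
  expect_equal(rownames(aln$groups$g2), c("B", "A", "C"))
  expect_equal(aln$groups$g2["C", ], c("T", "G"))

  dir <- withr::local_tempdir()
  dup <- write_fasta(c(A = "AC", A = "AG"), file.path(dir, "dup.fas"))
  expect_error(load_alignment_set(dup), "duplicate taxon")

  ragged <- write_fasta(c(A = "ACG", B = "AC"), file.path(dir, "rag.fas"))
  expect_error(load_alignment_set(ragged), "unequal sequence lengths")

  f1 <- write_fasta(c(A = "AC", B = "AG"), file.path(dir, "f1.fas"))
  f2 <- write_fasta(c(A = "TT", C = "TG"), file.path(dir, "f2.fas"))
  expect_error(load_alignment_set(c(f1, f2)), "differs")
})

test_that("data type policies validate the documented alphabets", {
  nuc <- data_type_policy("nucleotide")
  expect_setequal(nuc$valid_chars, c("A", "T", "C", "G", "U"))
  expect_false(nuc$case_sensitive)
  prot <- data_type_policy("protein")
  expect_length(prot$valid_chars, 20)
  expect_false("B" %in% prot$valid_chars)
  mol <- data_type_policy("molecular")
  expect_true(all(c("U", "W", "F") %in% mol$valid_chars))
  uni <- data_type_policy("universal")
  expect_true(uni$case_sensitive)
  expect_true(all(c("a", "A", "0", "9") %in% uni$valid_chars))
  # gap and missing characters are never valid states
  for (p in list(nuc, prot, mol, uni)) {
    expect_false(any(c("-", "?") %in% p$valid_chars))
    expect_equal(sort(p$missing_chars), c("-", "?"))
  }
})

test_that("single-column encodings follow the stated filter rules", {
  pol <- data_type_policy("nucleotide")

  # [A,A,C,T]: C and T are singletons and eliminated; A column survives
  enc <- one_hot_encode(column_aln(c("A", "A", "C", "T")), pol)
  expect_equal(nrow(enc$feature_map), 1L)
  expect_equal(enc$feature_map$char, "A")
  expect_equal(as.numeric(enc$X[, 1]), c(1, 1, 0, 0))

  # monomorphic column drops out entirely
  expect_error(one_hot_encode(column_aln(c("A", "A", "A", "A")), pol),
               "no informative features")
  # one unambiguous state plus gap/missing is still monomorphic
  expect_error(one_hot_encode(column_aln(c("A", "A", "-", "?")), pol),
               "no informative features")

  # include_singletons keeps both columns of [A,A,C,C]
  enc <- one_hot_encode(column_aln(c("A", "A", "C", "C")), pol,
                        include_singletons = TRUE)
  expect_equal(enc$feature_map$char, c("A", "C"))
  expect_equal(as.numeric(enc$X[, 1]), c(1, 1, 0, 0))
  expect_equal(as.numeric(enc$X[, 2]), c(0, 0, 1, 1))

  # bit_ct = 2 removes the G column of [A,A,C,C,G]
  enc <- one_hot_encode(column_aln(c("A", "A", "C", "C", "G")), pol,
                        include_singletons = TRUE, bit_ct = 2)
  expect_equal(enc$feature_map$char, c("A", "C"))
})

test_that("invalid characters are treated as missing and case is folded", {
  pol <- data_type_policy("nucleotide")
  # IUPAC ambiguity codes are missing data in nucleotide mode
  enc <- one_hot_encode(column_aln(c("a", "A", "R", "c", "C")), pol,
                        include_singletons = TRUE)
  expect_equal(enc$feature_map$char, c("A", "C"))
  expect_equal(as.numeric(enc$X[, 1]), c(1, 1, 0, 0, 0))
  expect_equal(as.numeric(enc$X[, 2]), c(0, 0, 0, 1, 1))

  # universal mode: case-sensitive, digits valid
  enc <- one_hot_encode(column_aln(c("a", "a", "A", "A", "0", "0")),
                        data_type_policy("universal"))
  expect_equal(enc$feature_map$char, c("0", "A", "a"))
})

test_that("taxa_subset restricts both encoding and filters", {
  aln <- column_aln(c("A", "A", "C", "C"))
  # over t1,t2 the column is monomorphic
  expect_error(one_hot_encode(aln, data_type_policy("nucleotide"),
                              taxa_subset = c("t1", "t2")),
               "no informative features")
  expect_error(one_hot_encode(aln, data_type_policy("nucleotide"),
                              taxa_subset = c("t1", "zz")),
               "zz")
})

test_that("feature map is dense, ordered and consistent with X", {
  aln <- make_aln(g1 = c(a = "AC", b = "AG", c = "TC", d = "TG"),
                  g2 = c(a = "T", b = "T", c = "A", d = "A"))
  enc <- one_hot_encode(aln, data_type_policy("nucleotide"),
                        include_singletons = TRUE)
  fm <- enc$feature_map
  expect_equal(fm$bit_index, seq_len(nrow(fm)) - 1L)
  ord <- order(match(fm$group, unique(fm$group)), fm$position, fm$char)
  expect_equal(ord, seq_len(nrow(fm)))
  expect_equal(colnames(enc$X), bit_column_names(fm))
  # each (taxon, position) row slice has at most one 1
  for (g in unique(fm$group)) for (p in unique(fm$position[fm$group == g])) {
    cols <- which(fm$group == g & fm$position == p)
    expect_true(all(Matrix::rowSums(enc$X[, cols, drop = FALSE]) <= 1))
  }
})

test_that("encoder matches a brute-force re-derivation on random alignments", {
  pol <- data_type_policy("nucleotide")
  withr::with_seed(2024, {
    for (trial in 1:25) {
      dir <- withr::local_tempdir()
      n <- sample(4:20, 1)
      paths <- random_aln_files(n, sample(5:50, 1), dir,
                                n_groups = sample(1:2, 1))
      aln <- load_alignment_set(paths)
      inc <- sample(c(TRUE, FALSE), 1)
      bc <- sample(1:3, 1)
      ref <- brute_force_feature_map(aln, pol, inc, bc)
      enc <- tryCatch(one_hot_encode(aln, pol, include_singletons = inc,
                                     bit_ct = bc),
                      error = function(e) NULL)
      if (is.null(ref)) {
        expect_null(enc)
      } else {
        expect_false(is.null(enc))
        expect_equal(enc$feature_map[, c("group", "position", "char")],
                     ref[, c("group", "position", "char")],
                     ignore_attr = TRUE)
        expect_equal(unname(Matrix::colSums(enc$X)), ref$count)
      }
    }
  })
})

test_that("encoding is invariant to input row order", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  seqs <- c(x = "ACGTAC", y = "ACGAAC", z = "TCGATT", w = "TCTATT")
  f1 <- write_fasta(seqs, file.path(d1, "g.fas"))
  f2 <- write_fasta(rev(seqs), file.path(d2, "g.fas"))
  e1 <- one_hot_encode(load_alignment_set(f1), data_type_policy("nucleotide"))
  e2 <- one_hot_encode(load_alignment_set(f2), data_type_policy("nucleotide"))
  expect_equal(e1$feature_map, e2$feature_map)
  expect_equal(as.matrix(e1$X), as.matrix(e2$X)[e1$taxa, ])
})
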