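test_that("read_fasta parses, normalizes case and maps U to T", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgu", ">b extra header words", "ACGT", "NNAC"), fa)
  rec <- read_fasta(fa, "dna")
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$seq, c("ACGT", "ACGTNNAC"))
})

test_that("read_fasta reads the packaged armadillidin fixture", {
  tab <- armadillidin_fixture("table2")
  expect_equal(nrow(tab), 18L)
  expect_true(all(c("A_vulgare_H", "A_vulgare_Q") %in% tab$id))
  expect_setequal(unique(unlist(strsplit(tab$seq, ""))),
                  intersect(unique(unlist(strsplit(tab$seq, ""))), AA20))
})

test_that("read_fasta rejects malformed and duplicated input", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a", "ACGT"), bad)
  expect_error(read_fasta(bad, "dna"), "line 1")
  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(read_fasta(dup, "dna"), "duplicate")
})

test_that("find_orfs recovers forced ORFs and respects strand symmetry", {
  o <- find_orfs(list(id = "x", seq = "ATGGGTTAA"), min_aa = 2L)
  fwd1 <- o[o$frame == 1L, ]
  expect_equal(fwd1$peptide, "MG")
  expect_equal(c(fwd1$start, fwd1$end), c(0L, 6L))
  # reverse-complement embedding gives the same peptide on the minus strand
  rc <- isoamp:::revcomp_dna("ATGGGTTAA")
  o2 <- find_orfs(list(id = "x", seq = rc), min_aa = 2L)
  expect_true("MG" %in% o2$peptide[o2$frame < 0L])
  expect_equal(nrow(find_orfs(list(id = "x", seq = "AT"), 1L)), 0L)
})

test_that("find_orfs equals a brute-force six-frame oracle on random input", {
  set.seed(11)
  for (k in 1:8) {
    s <- random_dna_str(300)
    got <- sort(find_orfs(list(id = "r", seq = s), min_aa = 5L)$peptide)
    expect_equal(got, ref_orf_peptides(s, 5L))
  }
})

test_that("longest_orf_peptide applies the documented tie-breaks", {
  # sixty-codon ORF dominates surrounding short ORFs
  set.seed(3)
  prec <- random_peptide(60)
  tx <- generate_transcriptome(synth_config(
    n_species = 1L, transcripts_per_species = 1L,
    planted = c(armadillidin = 1L), mutation_rate = 0, seed = 5L))
  top <- longest_orf_peptide(tx$transcripts[1L, ])
  expect_equal(top$seq, tx$truth$precursor_seq[1])
  # equal-length ORFs in frames +1 and +2: frame +1 wins
  s <- paste0("ATGGCTGCTTAA",          # frame +1: MAA
              "TTTTTTTTTTT")
  s2 <- paste0("TAAATGGCTGCCTAAG", "GATGGCAGCATAAT")
  o <- find_orfs(list(id = "t", seq = s2), min_aa = 3L)
  same_len <- o[nchar(o$peptide) == max(nchar(o$peptide)), ]
  expect_equal(same_len$frame[1], min(same_len$frame))
  # no ORF: explicit zero-row result, not an exception
  expect_equal(nrow(longest_orf_peptide(list(id = "e", seq = "TA"))), 0L)
})

test_that("collapse_redundant clusters by identity with partition invariant", {
  recs <- data.frame(id = c("a", "b"), seq = rep(strrep("ACGT", 30), 2))
  cl <- collapse_redundant(recs)
  expect_equal(length(unique(cl$representative_id)), 1L)
  expect_equal(nrow(cl), 2L)
  # 10% divergence splits at the 0.95 threshold
  set.seed(4)
  base <- random_dna_str(200)
  far <- mutate_sequence(base, 0.12, seed = 9L)
  cl2 <- collapse_redundant(data.frame(id = c("a", "b"),
                                       seq = c(base, far)), 0.95)
  expect_equal(length(unique(cl2$representative_id)), 2L)
})

test_that("collapse_redundant matches an all-pairs identity oracle", {
  set.seed(21)
  template <- random_dna_str(300)
  recs <- data.frame(
    id = sprintf("m%02d", 1:20),
    seq = vapply(1:20, function(i) mutate_sequence(template, 0.02, seed = i),
                 character(1)))
  cl <- collapse_redundant(recs, 0.95)
  expect_equal(length(unique(cl$representative_id)), 1L)
  expect_equal(sort(cl$member_id), sort(recs$id))
  # oracle: all pairwise identities (via Biostrings global alignment)
  # exceed the threshold, so a single cluster is the only consistent answer
  S <- diag(10, 5); dimnames(S) <- list(c("A","C","G","T","N"),
                                        c("A","C","G","T","N"))
  S[S == 0] <- -8
  for (i in c(2, 7, 13)) {
    pa <- Biostrings::pairwiseAlignment(recs$seq[1], recs$seq[i],
                                        substitutionMatrix = S,
                                        gapOpening = 10, gapExtension = 4,
                                        type = "global")
    idn <- Biostrings::nmatch(pa) / min(nchar(recs$seq[1]), nchar(recs$seq[i]))
    expect_gte(idn, 0.95)
  }
})
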