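test_that("local alignment reproduces hand-computed BLOSUM62 scores", {
  a <- local_align("GGGF", "GGGF")
  expect_equal(a$raw_score, 24)          # 3 x G:G(6) + F:F(6)
  expect_equal(a$identity_fraction, 1)
  # unrelated residues: best local score is the best single cell, never < 0
  expect_equal(local_align("AAAA", "GGGG")$raw_score, 0)
  expect_error(local_align("GGB1", "GGGF"), "letter")
})

test_that("alignment scores equal the reference DP on random pairs", {
  S <- blosum62_matrix()
  scheme <- scoring_scheme()
  set.seed(31)
  for (k in 1:25) {
    a <- random_peptide(sample(20:40, 1))
    b <- random_peptide(sample(20:40, 1))
    expect_equal(local_align(a, b, scheme)$raw_score,
                 ref_align_score(a, b, S, 11, 1, local = TRUE))
    expect_equal(global_align(a, b, scheme)$score,
                 ref_align_score(a, b, S, 11, 1, local = FALSE))
  }
})

test_that("local score is symmetric and self-score dominates mutants", {
  set.seed(5)
  for (k in 1:10) {
    a <- random_peptide(30)
    b <- random_peptide(25)
    expect_equal(local_align(a, b)$raw_score, local_align(b, a)$raw_score)
    m <- mutate_sequence(a, 0.2, seed = k)
    expect_gte(local_align(a, a)$raw_score, local_align(a, m)$raw_score)
  }
})

test_that("global alignment of GGGF/GGF has exactly one gap column", {
  aln <- global_align("GGGF", "GGF")
  gaps <- sum(strsplit(aln$rows[2], "")[[1]] == "-")
  expect_equal(nchar(aln$rows[1]), 4L)
  expect_equal(gaps, 1L)
  expect_equal(gsub("-", "", aln$rows[2]), "GGF")
})

test_that("E-value follows the Karlin-Altschul form", {
  sch <- scoring_scheme()
  expect_equal(evalue(0, 50, 1000, sch), sch$karlin_K * 50 * 1000)
  expect_equal(evalue(30, 50, 2000, sch), 2 * evalue(30, 50, 1000, sch))
  e <- evalue(10:40, 50, 1000, sch)
  expect_true(all(diff(e) < 0))
})

test_that("search returns self-match first and nothing on random database", {
  set.seed(8)
  q <- data.frame(id = "q", seq = random_peptide(60))
  db <- data.frame(id = c("hit", "r1", "r2"),
                   seq = c(q$seq, random_peptide(100), random_peptide(100)))
  hits <- homology_search(q, db)
  expect_equal(hits$subject_id[1], "hit")
  expect_true(all(hits$evalue <= 1e-10))
  db2 <- data.frame(id = sprintf("r%d", 1:12),
                    seq = vapply(rep(100, 12), random_peptide, character(1)))
  expect_equal(nrow(homology_search(q, db2)), 0L)
  expect_equal(nrow(homology_search(q[0, ], db2)), 0L)
})

test_that("reciprocal confirmation discards cross-family subjects", {
  refs <- armadillidin_fixture("family_refs")
  # a subject derived from the ALF reference is retained for the ALF query
  set.seed(13)
  alf_like <- mutate_sequence(refs$seq[refs$family == "alf"], 0.05, seed = 2L)
  db <- data.frame(id = c("alf_like", "decoy"),
                   seq = c(alf_like,
                           # decoy: armadillidin-derived subject that an ALF
                           # query must not keep after the back-search
                           refs$seq[refs$family == "armadillidin"]))
  hits <- homology_search(refs[, c("id", "seq")], db, evalue_max = 1e-6)
  conf <- reciprocal_confirm(hits, refs, db)
  kept <- conf[conf$subject_id == "alf_like", "query_id"]
  expect_true(all(grepl("^alf", kept)))
  cross <- conf[conf$subject_id == "decoy", "query_id"]
  expect_true(all(grepl("^armadillidin", cross)))
  expect_equal(nrow(reciprocal_confirm(hits[0, ], refs, db)), 0L)
})
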