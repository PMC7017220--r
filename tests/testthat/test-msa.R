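test_that("progressive MSA of identical sequences is gap-free", {
  seqs <- data.frame(id = c("a", "b", "c"), seq = rep("GHLGRPYIGGGG", 3))
  msa <- progressive_msa(seqs)
  expect_equal(msa$column_count, 12L)
  expect_true(all(msa$rows == "GHLGRPYIGGGG"))
})

test_that("ungapping MSA rows reproduces the inputs in order", {
  tab <- armadillidin_fixture("table2")
  sub <- tab[tab$id %in% armadillidiidae_ids(), ]
  msa <- progressive_msa(sub)
  expect_equal(msa$ids, sub$id)
  expect_equal(gsub("-", "", msa$rows), sub$seq)
  expect_gte(msa$column_count, max(nchar(sub$seq)))
})

test_that("trim_blocks applies the gap and block rules", {
  msa <- new_msa(c("a", "b"), c("AAAAAAAA", "AAAAAAAA"))
  expect_equal(trim_blocks(msa)$rows, msa$rows)
  # one 60%-gapped column inside a long block is removed
  rows <- c("AAAAA-AAAAA", "AAAAA-AAAAA", "AAAAA-AAAAA",
            "AAAAACAAAAA", "AAAAACAAAAA")
  tm <- trim_blocks(new_msa(letters[1:5], rows))
  expect_equal(tm$column_count, 10L)
  expect_true(all(!grepl("-", tm$rows)))
  expect_warning(trim_blocks(new_msa(c("a", "b"), c("A---", "-A--")),
                             max_gap_fraction = 0.4), "all columns")
})

test_that("trim_blocks equals a direct column filter oracle and is idempotent", {
  set.seed(17)
  base <- random_peptide(60)
  rows <- vapply(1:6, function(i) {
    ch <- strsplit(mutate_sequence(base, 0.1, seed = i), "")[[1]]
    ch[sample(60, 12)] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  msa <- new_msa(sprintf("s%d", 1:6), rows)
  tm <- trim_blocks(msa, 0.5, 5L)
  # oracle: gap-fraction filter, then runs >= 5 kept
  mat <- do.call(rbind, strsplit(rows, ""))
  keep <- colMeans(mat == "-") <= 0.5
  r <- rle(keep); r$values[r$values & r$lengths < 5] <- FALSE
  keep <- inverse.rle(r)
  expect_equal(tm$rows,
               apply(mat[, keep, drop = FALSE], 1, paste, collapse = ""))
  tm2 <- trim_blocks(tm, 0.5, 5L)
  expect_equal(tm2$rows, tm$rows)
})

test_that("column consensus emits residues, classes and gaps correctly", {
  msa <- new_msa(c("a", "b"), c("GGGF", "GGGF"))
  cons <- column_consensus(msa, 0.70)
  expect_equal(cons$consensus, "GGGF")
  expect_equal(cons$column_conservation, rep(1, 4))
  # residues sharing neither identity nor class at 0.5 < 0.7: all '-'
  cons2 <- column_consensus(new_msa(c("a", "b"), c("GKE", "APC")), 0.70)
  expect_equal(cons2$consensus, "---")
  # class agreement without residue agreement emits the modal class residue
  cons3 <- column_consensus(new_msa(letters[1:4], c("L", "L", "V", "D")), 0.70)
  expect_equal(cons3$consensus, "L")   # aliphatic class at 3/4
})

test_that("Armadillidiidae consensus carries the family motif signature", {
  tab <- armadillidin_fixture("table2")
  sub <- tab[tab$id %in% armadillidiidae_ids(), ]
  cons <- column_consensus(progressive_msa(sub), 0.70)
  expect_true(grepl("RPYIGGGG", cons$consensus))
  n_gggf <- length(gregexpr("GGGF", cons$consensus)[[1]])
  expect_gte(n_gggf, 3L)
  # consensus emission is consistent with the conservation vector
  ch <- strsplit(cons$consensus, "")[[1]]
  expect_true(all((ch != "-") == (cons$column_conservation >= 0.70)))
})

test_that("consensus is robust to input order", {
  tab <- armadillidin_fixture("table2")
  sub <- tab[tab$id %in% armadillidiidae_ids(), ]
  set.seed(9)
  for (k in 1:3) {
    perm <- sample(nrow(sub))
    cons <- column_consensus(progressive_msa(sub[perm, ]), 0.70)
    expect_true(grepl("RPYIGGGG", cons$consensus))
    expect_gte(length(gregexpr("GGGF", cons$consensus)[[1]]), 3L)
  }
})
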