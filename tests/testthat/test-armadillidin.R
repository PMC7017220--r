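test_that("mature extraction respects the signal annotation", {
  tab <- armadillidin_fixture("table2")
  h <- tab$seq[tab$id == "A_vulgare_H"]
  prec <- list(id = "AvH", seq = paste0("MKFAALVALLAVFAAFASA", h))
  sp <- detect_signal_peptide(prec$seq)
  mat <- extract_mature(prec, sp)
  expect_equal(mat$id, "AvH_mature")
  expect_equal(nchar(mat$seq), 53L)
  expect_equal(mat$seq, h)
  # zero cleavage index is the identity
  id_sig <- structure(list(present = TRUE, cleavage_index = 0L,
                           hydropathy_score = 0), class = "isoamp_signal")
  expect_equal(extract_mature(list(id = "x", seq = h), id_sig)$seq, h)
  absent <- structure(list(present = FALSE, cleavage_index = NA_integer_,
                           hydropathy_score = 0), class = "isoamp_signal")
  expect_error(extract_mature(list(id = "x", seq = h), absent), "mature")
})

test_that("G-run scanning reproduces hand-scanned fixture motifs", {
  sc <- scan_g_runs("GGGF")
  expect_equal(nrow(sc$g_runs), 1L)
  expect_equal(sc$g_runs$length, 3L)
  expect_equal(sc$gggf_count, 1L)
  sc2 <- scan_g_runs("AGGA")
  expect_equal(sc2$g_runs$length, 2L)
  expect_equal(nrow(sc2$gggx_motifs), 0L)
  tab <- armadillidin_fixture("table2")
  sv <- scan_g_runs(tab$seq[tab$id == "A_versicolor"])
  expect_equal(sv$gggf_count, 6L)
  expect_true(all(sv$gggx_motifs$x %in% c("F", "S")))
  # printed per-species run counts under the runs >= 2 convention
  expect_equal(nrow(scan_g_runs(tab$seq[tab$id == "C_elongata"])$g_runs), 7L)
  expect_equal(nrow(scan_g_runs(tab$seq[tab$id == "P_dispar"])$g_runs), 6L)
})

test_that("G-run scanning equals the enumeration oracle on random strings", {
  set.seed(19)
  for (k in 1:300) {
    s <- paste(sample(c("G", "G", "G", "F", "R", "Y", "A"), 40, TRUE),
               collapse = "")
    runs <- scan_g_runs(s)$g_runs
    oracle <- ref_g_runs(s)
    expect_equal(nrow(runs), length(oracle))
    if (length(oracle)) {
      expect_equal(runs$start, vapply(oracle, `[[`, numeric(1), "start"))
      expect_equal(runs$length, vapply(oracle, `[[`, numeric(1), "len"))
    }
    # appending a non-G residue never changes existing runs
    runs2 <- scan_g_runs(paste0(s, "A"))$g_runs
    expect_equal(runs2$start, runs$start)
    expect_equal(runs2$length, runs$length)
  }
})

test_that("composition profile flags over-represented residues strictly", {
  expect_equal(composition_profile("GGGG")$overrepresented, character(0))
  # strictly >10% flags both letters here: A is 2/11 = 18% of the sequence
  expect_setequal(composition_profile("ARRRRRRRRRA")$overrepresented,
                  c("A", "R"))
  tab <- armadillidin_fixture("table2")
  cp <- composition_profile(tab$seq[tab$id == "A_vulgare_H"])
  expect_gt(cp$fractions[["R"]], 0.10)
  expect_true("R" %in% cp$overrepresented)
  expect_equal(sum(cp$counts), 53L)
  expect_equal(sum(cp$fractions), 1)
})

test_that("average mass matches free glycine, the synthetic peptides, and additivity", {
  expect_equal(round(average_mass("G"), 2), 75.07)
  syn <- armadillidin_fixture("synthetic_peptides")
  expect_equal(round(average_mass(syn$seq[syn$id == "armadillidin_CE"]), 1),
               5150.5)
  expect_equal(round(average_mass(syn$seq[syn$id == "armadillidin_PP"]), 1),
               5307.6)
  set.seed(23)
  a <- random_peptide(12); b <- random_peptide(9)
  expect_equal(average_mass(paste0(a, b)),
               average_mass(a) + average_mass(b) - 18.01524,
               tolerance = 1e-9)
  expect_error(average_mass("GXG"), "mass undefined")
})

test_that("theoretical pI reproduces printed values and closes the charge", {
  tab <- armadillidin_fixture("table2")
  pi_off <- isoelectric_point(tab$seq[tab$id == "A_officinalis"])
  expect_equal(pi_off, 8.6, tolerance = 0.15)
  pi_ver <- isoelectric_point(tab$seq[tab$id == "A_versicolor"])
  expect_equal(pi_ver, 12.1, tolerance = 0.15)
  for (s in tab$seq[c(1, 9, 13)]) {
    expect_lt(abs(net_charge(s, isoelectric_point(s))), 1e-4)
  }
})

test_that("adding an arginine never lowers the pI", {
  tab <- armadillidin_fixture("table2")
  for (s in tab$seq[c(2, 9, 16)]) {
    expect_gte(isoelectric_point(paste0(s, "R")) + 1e-6,
               isoelectric_point(s))
  }
})

test_that("characterization table matches every printed value", {
  tab <- armadillidin_fixture("table2")
  pc <- physicochem_table(tab)
  m <- match(table2_expected$id, pc$id)
  expect_false(anyNA(m))
  expect_equal(pc$length[m], table2_expected$length)
  expect_equal(pc$gly_pct[m], table2_expected$gly)
  expect_true(all(abs(pc$avg_mass[m] - table2_expected$mw) <= 0.15))
  expect_true(all(abs(pc$pI[m] - table2_expected$pi) <= 0.15))
  # row values do not depend on record order
  pc2 <- physicochem_table(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(pc2[match(pc$id, pc2$id), -1], pc[, -1],
               ignore_attr = TRUE)
})

test_that("arginine over-representation counting is strict and per organism", {
  expect_equal(arg_overrepresentation_count(character(0)), 0L)
  expect_equal(arg_overrepresentation_count(c(x = strrep("R", 10))), 1L)
  expect_equal(arg_overrepresentation_count(c(x = strrep("R", 1))), 1L)
  org <- armadillidin_by_organism()
  expect_equal(length(org), 17L)
  # exactly at the threshold is not over-represented (strict rule)
  at10 <- paste0(strrep("R", 1), strrep("G", 9))
  expect_equal(arg_overrepresentation_count(c(x = at10)), 0L)
})
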