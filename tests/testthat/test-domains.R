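test_that("hydropathy profile matches constant sequences and a naive oracle", {
  expect_equal(hydropathy_profile(strrep("I", 12)), rep(4.5, 12))
  expect_equal(hydropathy_profile(strrep("R", 12)), rep(-4.5, 12))
  set.seed(2)
  s <- random_peptide(20)
  prof <- hydropathy_profile(s, 9L)
  kd <- c(A=1.8,R=-4.5,N=-3.5,D=-3.5,C=2.5,Q=-3.5,E=-3.5,G=-0.4,H=-3.2,
          I=4.5,L=3.8,K=-3.9,M=1.9,F=2.8,P=-1.6,S=-0.8,T=-0.7,W=-0.9,
          Y=-1.3,V=4.2)
  v <- kd[strsplit(s, "")[[1]]]
  naive <- vapply(seq_len(20), function(i)
    mean(v[max(1, i - 4):min(20, i + 4)]), numeric(1))
  expect_equal(prof, unname(naive))
  expect_error(hydropathy_profile(s, 8L), "odd")
})

test_that("signal peptide detection finds A-X-A cleavage sites", {
  # classical constructed precursor: cleavage after the ...A-S-A motif
  sp <- detect_signal_peptide(paste0("MKFAIVALLAVVAAASA",
                                     "GHLGRPYIGGGGGFNRGGGFHRGG"))
  expect_true(sp$present)
  expect_equal(sp$cleavage_index, 17L)
  expect_gte(sp$hydropathy_score, 1.5)
  # hydrophilic N-terminus: no signal
  sp2 <- detect_signal_peptide(paste0(strrep("R", 20), random_peptide(20)))
  expect_false(sp2$present)
  expect_true(is.na(sp2$cleavage_index))
})

test_that("synthetic precursors cleave after the 19-residue signal", {
  sim <- generate_transcriptome(synth_config(
    n_species = 3L, transcripts_per_species = 3L, mutation_rate = 0,
    seed = 12L))
  for (i in seq_len(nrow(sim$truth))) {
    sp <- detect_signal_peptide(sim$truth$precursor_seq[i])
    expect_true(sp$present)
    expect_equal(sp$cleavage_index, 19L)
    mat <- extract_mature(list(id = "p", seq = sim$truth$precursor_seq[i]), sp)
    expect_equal(mat$seq, sim$truth$mature_seq[i])
  }
})

test_that("ALF validation applies the cysteine, length and hydropathy rules", {
  refs <- armadillidin_fixture("family_refs")
  alf <- refs$seq[refs$family == "alf"]
  ann <- validate_alf(alf)
  expect_equal(ann$family, "ALF")
  expect_equal(ann$cys_positions, c(28L, 53L))
  # Cys -> Ser knocks out the pair rule
  no_cys <- gsub("C", "S", alf)
  ann2 <- validate_alf(no_cys)
  expect_equal(ann2$family, "none")
  expect_false(ann2$checks[["cys_pair"]])
  # short fragment fails the length rule
  ann3 <- validate_alf(substr(alf, 1, 40))
  expect_equal(ann3$family, "none")
  expect_false(ann3$checks[["length"]])
})

test_that("WAP validation detects C-terminal cysteine-rich windows", {
  refs <- armadillidin_fixture("family_refs")
  cru <- refs$seq[refs$family == "crustin"]
  ann <- validate_wap(cru)
  expect_equal(ann$family, "crustin")
  expect_equal(ann$checks[["wap_count"]], 1)
  expect_equal(validate_wap(gsub("C", "A", cru))$family, "none")
  # two concatenated WAP regions are counted as two windows
  double <- paste0(cru, substr(cru, 41, nchar(cru)))
  expect_equal(validate_wap(double)$checks[["wap_count"]], 2)
})

test_that("family-level conserved cysteine columns are flagged", {
  refs <- armadillidin_fixture("family_refs")
  cru <- refs$seq[refs$family == "crustin"]
  fam <- data.frame(
    id = sprintf("c%d", 1:5),
    seq = vapply(1:5, function(i) {
      cys <- as.integer(gregexpr("C", cru)[[1]])
      mutate_sequence(cru, 0.08, seed = i, protect = cys)
    }, character(1)))
  msa <- progressive_msa(fam)
  fl <- flag_conserved_cys(msa, n_cys = 12L, min_fraction = 0.9)
  expect_true(fl$flag)
  expect_gte(fl$n_conserved_cys, 12L)
})

test_that("family annotations are disjoint on the packaged fixtures", {
  refs <- armadillidin_fixture("family_refs")
  tab <- armadillidin_fixture("table2")
  for (s in c(refs$seq, tab$seq)) {
    a <- validate_alf(s)
    w <- validate_wap(s)
    expect_false(a$family == "ALF" && w$family == "crustin")
  }
})
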