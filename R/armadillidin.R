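# Armadillidin mature-peptide characterization: GGGX motif scanning,
# residue over-representation, average molecular mass and theoretical pI.
# Masses and pKa values are pinned in R/constants.R (IUPAC average residue
# masses; Bjellqvist pKa set) so that reported values are bit-stable.

#' Extract the mature peptide from a precursor
#'
#' @param precursor A peptide record (single-row `data.frame` or
#'   `list(id=, seq=)`).
#' @param signal A signal annotation from [detect_signal_peptide()] with
#'   `present = TRUE`; an absent signal is an error directing the caller to
#'   treat the input as already mature.
#' @return A single-row `data.frame` with `id` (suffixed `_mature`) and
#'   `seq` (residues from the cleavage index to the end).
#' @export
extract_mature <- function(precursor, signal) {
  precursor <- as_record(precursor)
  if (!isTRUE(signal$present)) {
    stop("no signal peptide detected for ", precursor$id,
         "; treat the input as already mature")
  }
  data.frame(id = paste0(precursor$id, "_mature"),
             seq = substr(precursor$seq, signal$cleavage_index + 1L,
                          nchar(precursor$seq)))
}

#' Scan the glycine runs and GGGX motifs of a peptide
#'
#' Glycine runs are maximal stretches of at least two consecutive G. Every
#' run of length >= 3 contributes one GGGX motif whose X is the residue
#' immediately after the run (`*` marks a terminal run).
#'
#' @param seq Non-empty peptide string.
#' @return A list of class `isoamp_motifscan` with fields `g_runs`
#'   (`data.frame`: `start` 0-based, `length`, `following_residue`),
#'   `gggx_motifs` (`data.frame`: `position`, `x`), `gggf_count` and
#'   `fourth_residue_table` (named occurrence counts of X).
#' @export
scan_g_runs <- function(seq) {
  stopifnot(nzchar(seq))
  m <- gregexpr("G{2,}", seq)[[1]]
  if (m[1] == -1L) {
    runs <- data.frame(start = integer(0), length = integer(0),
                       following_residue = character(0))
  } else {
    st <- as.integer(m); len <- attr(m, "match.length")
    foll <- ifelse(st + len <= nchar(seq),
                   substring(seq, st + len, st + len), "*")
    runs <- data.frame(start = st - 1L, length = len,
                       following_residue = foll)
  }
  idx <- which(runs$length >= 3L)
  motifs <- data.frame(position = runs$start[idx],
                       x = runs$following_residue[idx])
  tab <- table(motifs$x)
  structure(list(
    g_runs = runs, gggx_motifs = motifs,
    gggf_count = sum(motifs$x == "F"),
    fourth_residue_table = setNames(as.integer(tab), names(tab))),
    class = "isoamp_motifscan")
}

#' Residue composition and over-represented residues
#'
#' A residue other than glycine is over-represented when it makes up
#' strictly more than `threshold` of the sequence.
#'
#' @param seq Non-empty peptide string.
#' @param threshold Over-representation threshold (default 0.10, strict).
#' @return A list of class `isoamp_composition` with `counts`, `fractions`
#'   (over the 20 standard letters plus X) and `overrepresented`.
#' @export
composition_profile <- function(seq, threshold = 0.10) {
  stopifnot(nzchar(seq))
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = c(AA_LETTERS, "X")))
  counts <- setNames(as.integer(counts), names(counts))
  fractions <- counts / length(chars)
  over <- names(fractions)[fractions > threshold & names(fractions) != "G"]
  structure(list(counts = counts, fractions = fractions,
                 overrepresented = over),
            class = "isoamp_composition")
}

#' Average molecular mass of a peptide
#'
#' Sum of isotope-averaged residue masses plus one water; free, unmodified
#' termini (no C-terminal amidation).
#'
#' @param seq Peptide over the 20 standard letters (X has no defined mass
#'   and is an error).
#' @return Average mass in Da (full precision; round for reporting).
#' @export
average_mass <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  m <- RESIDUE_AVG_MASS[chars]
  if (anyNA(m)) stop("mass undefined for letter: ", chars[is.na(m)][1])
  sum(m) + WATER_AVG_MASS
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch model over the N and C termini and the D, E, C, Y,
#' H, K, R side chains with the Bjellqvist pKa set (the set behind the
#' ProtParam theoretical pI; terminal pKa values depend on the terminal
#' residues).
#'
#' @param seq Peptide string.
#' @param pH pH value(s).
#' @return Net charge (vectorized over `pH`).
#' @export
net_charge <- function(seq, pH) {
  chars <- strsplit(seq, "")[[1]]
  nt <- PK_NTERM[chars[1]]
  if (is.na(nt)) nt <- PK_NTERM_DEFAULT
  ct <- PK_CTERM[chars[length(chars)]]
  if (is.na(ct)) ct <- PK_CTERM_DEFAULT
  q <- 1 / (1 + 10^(pH - nt)) - 1 / (1 + 10^(ct - pH))
  for (a in names(PK_SIDE_POS)) {
    n <- sum(chars == a)
    if (n) q <- q + n / (1 + 10^(pH - PK_SIDE_POS[[a]]))
  }
  for (a in names(PK_SIDE_NEG)) {
    n <- sum(chars == a)
    if (n) q <- q - n / (1 + 10^(PK_SIDE_NEG[[a]] - pH))
  }
  unname(q)
}

#' Theoretical isoelectric point
#'
#' Root of the net-charge curve, found by bisection on pH 0-14 to a charge
#' tolerance of 1e-4. The charge function is strictly decreasing in pH, so
#' the root is unique.
#'
#' @param seq Peptide over the standard letters.
#' @return pI in pH units (full precision; round for reporting).
#' @export
isoelectric_point <- function(seq) {
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(seq, mid)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Physico-chemical characterization table
#'
#' One row per input mature peptide: residue length, average molecular mass
#' (Da), glycine percentage and theoretical pI, with masses, percentages and
#' pI rounded half-up to one decimal (printed-table convention).
#'
#' @param seqs Record `data.frame` with columns `id`, `seq`.
#' @return A `data.frame` with columns `id`, `length`, `avg_mass`,
#'   `gly_pct`, `pI`.
#' @export
physicochem_table <- function(seqs) {
  stopifnot(nrow(seqs) >= 1)
  data.frame(
    id = seqs$id,
    length = nchar(seqs$seq),
    avg_mass = round_half_up(vapply(seqs$seq, average_mass, numeric(1)), 1),
    gly_pct = round_half_up(
      100 * vapply(seqs$seq,
                   function(s) sum(strsplit(s, "")[[1]] == "G") / nchar(s),
                   numeric(1)), 1),
    pI = round_half_up(vapply(seqs$seq, isoelectric_point, numeric(1)), 1),
    row.names = NULL)
}

#' Count organisms whose mature armadillidin over-represents arginine
#'
#' @param species_to_seq Named character vector (organism -> mature peptide,
#'   one sequence per organism).
#' @param threshold Strict fraction threshold (default 0.10).
#' @return Number of organisms whose arginine fraction is strictly greater
#'   than `threshold`.
#' @export
arg_overrepresentation_count <- function(species_to_seq, threshold = 0.10) {
  if (length(species_to_seq) == 0L) return(0L)
  frac <- vapply(species_to_seq, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch == "R") / length(ch)
  }, numeric(1))
  sum(frac > threshold)
}

#' Packaged armadillidin fixtures
#'
#' Returns the packaged FASTA fixtures: `"table2"` (the 18 mature
#' armadillidin sequences of 17 terrestrial isopod organisms; the
#' *A. vulgare* H and Q variants are suffixed `_H`/`_Q`),
#' `"synthetic_peptides"` (the two synthetic peptides armadillidin CE and
#' PP used in growth-inhibition assays) and `"family_refs"` (the ALF,
#' crustin and armadillidin reference peptides used as homology-search
#' queries; the ALF and crustin entries are synthetic constructions to the
#' family rules, the armadillidin entry is the *A. vulgare* H mature
#' peptide).
#'
#' @param which One of `"table2"`, `"synthetic_peptides"`, `"family_refs"`.
#' @return A record `data.frame`; for `"family_refs"` with an extra
#'   `family` column.
#' @export
armadillidin_fixture <- function(which = c("table2", "synthetic_peptides",
                                           "family_refs")) {
  which <- match.arg(which)
  fname <- switch(which,
    table2 = "table2_armadillidins.fasta",
    synthetic_peptides = "synthetic_peptides.fasta",
    family_refs = "family_refs_synthetic.fasta")
  path <- system.file("extdata", fname, package = "isoamp", mustWork = TRUE)
  rec <- read_fasta(path, "protein")
  if (which == "family_refs") {
    rec$family <- sub("_.*$", "", rec$id)
  }
  rec
}

#' Organisms of the Armadillidiidae family in the packaged fixture
#'
#' The family comprises the *Armadillidium* species and *Eluma
#' purpurascens*; the *A. vulgare* H variant is used for the single-sequence
#' view.
#'
#' @return Character vector of fixture ids.
#' @export
armadillidiidae_ids <- function() {
  c("A_assimile", "A_depressum", "A_maculatum", "A_nasatum",
    "A_tunisiense", "A_versicolor", "A_vulgare_H", "E_purpurascens")
}

#' One mature armadillidin per organism from the packaged fixture
#'
#' @return Named character vector (17 organisms; the *A. vulgare* H variant
#'   represents that species).
#' @export
armadillidin_by_organism <- function() {
  tab <- armadillidin_fixture("table2")
  tab <- tab[tab$id != "A_vulgare_Q", ]
  org <- sub("_H$", "", tab$id)
  setNames(tab$seq, org)
}
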