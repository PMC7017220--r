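# Rule-based domain and signal-peptide annotation. All thresholds are
# explicit arguments with defaults pinned to the package's documented
# operationalization of the family hallmarks: ALF = hydrophobic N-terminal
# mature region with an early cysteine pair; crustin = C-terminal
# cysteine-rich WAP domain; armadillidin = glycine-rich mature peptide in
# GGGX runs behind a conserved signal peptide.

kd_values <- function(seq) {
  v <- KD_SCALE[strsplit(seq, "")[[1]]]
  v[is.na(v)] <- 0   # X and other ambiguity codes are neutral
  unname(v)
}

#' Kyte-Doolittle hydropathy profile
#'
#' Centered sliding-window mean of Kyte-Doolittle values; at the ends the
#' window is truncated to the available residues.
#'
#' @param seq Peptide string with `nchar(seq) >= window`.
#' @param window Odd window size (default 9).
#' @return Numeric vector of length `nchar(seq)`.
#' @export
hydropathy_profile <- function(seq, window = 9L) {
  if (window %% 2L == 0L) stop("window must be odd")
  v <- kd_values(seq)
  n <- length(v)
  stopifnot(n >= window)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# best (maximal) mean over all `w`-residue windows of seq[1..upto]
best_window_mean <- function(v, w) {
  n <- length(v)
  if (n < w) return(mean(v))
  cs <- c(0, cumsum(v))
  max((cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w)
}

# quality of the residue at a cleavage-site position: signal peptidase I
# strongly prefers alanine at -3 and -1, tolerates other small residues
small_residue_quality <- c(A = 2, G = 1, S = 1, C = 0.5, T = 0.5)

#' Detect an N-terminal secretion signal peptide
#'
#' Hydropathy heuristic in the spirit of classical signal peptide
#' predictors: candidate cleavage sites between positions `min_cleave` and
#' `max_cleave` are scored; a signal is called when the region before the
#' cleavage site has a sufficiently hydrophobic core (best 8-residue window
#' mean of Kyte-Doolittle values) and the residues at positions -3 and -1
#' relative to cleavage are small (`A, G, S, C, T`). Passing candidates are
#' ranked by small-residue quality (A preferred over G/S over C/T) minus
#' the mean hydropathy of the five residues after the cleavage site (the
#' mature peptide should leave the hydrophobic core, which keeps the site
#' from drifting into a hydrophobic mature N-terminus); remaining ties go
#' to the longest signal.
#'
#' @param seq Peptide string of at least 25 residues.
#' @param min_hydropathy Minimum mean hydropathy of the best 8-residue core
#'   (default 1.5).
#' @param min_cleave,max_cleave Candidate cleavage range (0-based index of
#'   the first mature residue; defaults 10 and 40).
#' @return A list of class `isoamp_signal` with fields `present`,
#'   `cleavage_index` (0-based first mature residue, `NA` when absent) and
#'   `hydropathy_score` (core mean of the returned candidate, or the best
#'   core seen when absent).
#' @export
detect_signal_peptide <- function(seq, min_hydropathy = 1.5,
                                  min_cleave = 10L, max_cleave = 40L) {
  stopifnot(nchar(seq) >= 25L)
  v <- kd_values(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(v)
  best <- NULL
  best_core_seen <- -Inf
  for (cleave in min_cleave:min(max_cleave, n - 1L)) {
    core <- best_window_mean(v[seq_len(cleave)], 8L)
    if (core > best_core_seen) best_core_seen <- core
    q3 <- small_residue_quality[chars[cleave - 2L]]   # position -3 (1-based)
    q1 <- small_residue_quality[chars[cleave]]        # position -1
    if (is.na(q3) || is.na(q1)) next
    if (core < min_hydropathy) next
    after <- v[(cleave + 1L):min(n, cleave + 5L)]
    score <- q3 + q1 - mean(after)
    cand <- list(cleavage_index = cleave, score = score, core = core)
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$cleavage_index > best$cleavage_index)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(structure(list(present = FALSE, cleavage_index = NA_integer_,
                          hydropathy_score = best_core_seen),
                     class = "isoamp_signal"))
  }
  structure(list(present = TRUE, cleavage_index = best$cleavage_index,
                 hydropathy_score = best$core),
            class = "isoamp_signal")
}

#' Extract the mature region given a signal annotation
#' @keywords internal
mature_region <- function(seq, signal) {
  if (!is.null(signal) && isTRUE(signal$present)) {
    substr(seq, signal$cleavage_index + 1L, nchar(seq))
  } else {
    seq
  }
}

cys_positions <- function(seq) {
  p <- gregexpr("C", seq, fixed = TRUE)[[1]]
  if (p[1] == -1L) integer(0) else as.integer(p) - 1L   # 0-based
}

new_annotation <- function(family, domain_span, cys, checks) {
  structure(list(family = family, domain_span = domain_span,
                 cys_positions = cys, checks = checks),
            class = "isoamp_annotation")
}

#' Validate a candidate as an anti-lipopolysaccharide factor (ALF)
#'
#' The mature region must carry at least two cysteines with some pair
#' separated by 15-55 residues (the LPS-binding loop; any pair qualifies,
#' which keeps the rule robust to incidental cysteines inside or outside
#' the loop), have a length of 70-160 residues (an 8-14 kDa single-domain
#' peptide) and a hydrophobic N-terminal stretch (mean Kyte-Doolittle of
#' the first 25 mature residues >= 0.5).
#'
#' @param seq Candidate peptide (precursor or mature).
#' @param signal A signal annotation from [detect_signal_peptide()], or
#'   `NULL` to treat `seq` as already mature.
#' @return An `isoamp_annotation` with `family` `"ALF"` or `"none"`,
#'   the cysteine positions of the mature region (0-based) and the
#'   individual rule outcomes in `checks`.
#' @export
validate_alf <- function(seq, signal = NULL) {
  mat <- mature_region(seq, signal)
  cys <- cys_positions(mat)
  pair <- NULL
  if (length(cys) >= 2L) {
    for (i in seq_len(length(cys) - 1L)) {
      sep <- cys[(i + 1L):length(cys)] - cys[i]
      j <- which(sep >= 15L & sep <= 55L)
      if (length(j)) { pair <- c(cys[i], cys[i + j[1]]); break }
    }
  }
  checks <- c(
    cys_pair = !is.null(pair),
    length = nchar(mat) >= 70L && nchar(mat) <= 160L,
    hydrophobic_nterm = nchar(mat) >= 25L &&
      mean(kd_values(substr(mat, 1L, 25L))) >= 0.5
  )
  fam <- if (all(checks)) "ALF" else "none"
  span <- if (all(checks)) c(pair[1], pair[2] + 1L) else
    c(NA_integer_, NA_integer_)
  new_annotation(fam, span, cys, checks)
}

# all disjoint cysteine-rich windows: minimal windows of length in
# [min_win, max_win] containing >= min_cys cysteines, scanned left to right
wap_windows <- function(seq, min_cys = 8L, min_win = 35L, max_win = 60L) {
  cys <- cys_positions(seq)
  n <- nchar(seq)
  wins <- list()
  i <- 0L
  while (i <= n - min_win) {
    found <- NULL
    for (w in min_win:max_win) {
      if (i + w > n) break
      k <- sum(cys >= i & cys < i + w)
      if (k >= min_cys) { found <- c(i, i + w); break }  # minimal length
    }
    if (!is.null(found)) {
      wins[[length(wins) + 1L]] <- found
      i <- found[2]
    } else {
      i <- i + 1L
    }
  }
  wins
}

#' Validate a candidate as a crustin (WAP domain check)
#'
#' A crustin must carry a whey-acidic-protein-like domain near its C
#' terminus: a window of 35-60 residues containing at least `min_cys`
#' cysteines and overlapping the C-terminal half of the peptide. All
#' disjoint qualifying windows over the whole peptide are reported in
#' `checks` (`wap_count`) for multi-WAP detection.
#'
#' @param seq Candidate peptide (mature region).
#' @param min_cys Minimum cysteines per WAP window (default 8; canonical
#'   single WAP domains have 8, the family-level alignment conserves 12).
#' @return An `isoamp_annotation` with `family` `"crustin"` or `"none"`; the
#'   `domain_span` is the first qualifying window in the C-terminal half.
#' @export
validate_wap <- function(seq, min_cys = 8L) {
  wins <- wap_windows(seq, min_cys = min_cys)
  half <- nchar(seq) %/% 2L
  in_cterm <- Filter(function(w) w[2] > half, wins)
  ok <- length(in_cterm) > 0L
  checks <- c(wap_cterm = ok, wap_count = length(wins))
  span <- if (ok) in_cterm[[1]] else c(NA_integer_, NA_integer_)
  cys <- if (ok) {
    cp <- cys_positions(seq)
    cp[cp >= span[1] & cp < span[2]]
  } else cys_positions(seq)
  new_annotation(if (ok) "crustin" else "none", span, cys, checks)
}

#' Validate a candidate as an armadillidin
#'
#' Armadillidins are linear glycine-rich peptides: the mature region must be
#' at least 25% glycine and contain at least two glycine runs of length >= 3
#' (GGGX motifs).
#'
#' @param seq Candidate peptide (precursor or mature).
#' @param signal Optional signal annotation (see [validate_alf()]).
#' @param min_gly_fraction Minimum mature glycine fraction (default 0.25).
#' @param min_g_runs Minimum number of glycine runs of length >= 3.
#' @return An `isoamp_annotation` with `family` `"armadillidin"` or
#'   `"none"`.
#' @export
validate_armadillidin <- function(seq, signal = NULL,
                                  min_gly_fraction = 0.25, min_g_runs = 2L) {
  mat <- mature_region(seq, signal)
  scan <- scan_g_runs(mat)
  gly <- sum(strsplit(mat, "")[[1]] == "G") / nchar(mat)
  checks <- c(gly_rich = gly >= min_gly_fraction,
              g_runs = nrow(scan$gggx_motifs) >= min_g_runs)
  fam <- if (all(checks)) "armadillidin" else "none"
  new_annotation(fam, c(0L, nchar(mat)), cys_positions(mat), checks)
}

#' Flag family-level conserved cysteine columns
#'
#' Given an alignment of one family, counts alignment columns in which at
#' least `min_fraction` of the rows carry a cysteine; the flag is set when
#' at least `n_cys` such columns exist. This captures the "12 conserved
#' cysteines" view of crustin WAP regions as a family-level conservation
#' statement rather than a per-sequence requirement.
#'
#' @param msa An `isoamp_msa` of family members.
#' @param n_cys Required number of conserved cysteine columns (default 12).
#' @param min_fraction Per-column conservation level (default 0.9).
#' @return A list with `n_conserved_cys` and logical `flag`.
#' @export
flag_conserved_cys <- function(msa, n_cys = 12L, min_fraction = 0.9) {
  mat <- msa_matrix(msa)
  ncc <- if (ncol(mat) == 0L) 0L else sum(colMeans(mat == "C") >= min_fraction)
  list(n_conserved_cys = as.integer(ncc), flag = ncc >= n_cys)
}
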