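# Family length filters and crustin type I/II classification. Type
# thresholds sit inside the empty gap between the published value ranges of
# glycine-rich type II crustins (region 130-166 aa, 24.6-32.3% G, 3-11
# repeated tetrapeptides) and the short-region type I clusters (<= 62 aa,
# <= 9.8% G, no repeats), so any sequence matching either published range is
# classified unambiguously.

#' Keep records at or above a minimum length
#'
#' @param records Record `data.frame` with columns `id`, `seq`.
#' @param min_len Minimum residue count (boundary inclusive).
#' @return The filtered records, input order preserved.
#' @export
length_filter <- function(records, min_len) {
  stopifnot(min_len >= 1)
  records[nchar(records$seq) >= min_len, , drop = FALSE]
}

#' Detect the glycine-rich region of a peptide
#'
#' Finds the `window`-residue window with the highest glycine density; if
#' that window reaches `min_density` the region is grown outward in adjacent
#' windows (partial windows at the sequence edges allowed), each of which
#' must itself hold `min_density`, and the result is the union of accepted
#' windows.
#'
#' @param seq Peptide string with `nchar(seq) >= window`.
#' @param min_density Minimum glycine fraction of a window (default 0.20).
#' @param window Window length in residues (default 20).
#' @return A list of class `isoamp_grich` with fields `region_span` (0-based
#'   half-open; `c(0, 0)` when no window qualifies), `region_size`,
#'   `gly_fraction` (over the region), `region_seq` and
#'   `repetitive_tetrapeptide_count`.
#' @export
detect_grich_region <- function(seq, min_density = 0.20, window = 20L) {
  n <- nchar(seq)
  stopifnot(n >= window)
  isg <- strsplit(seq, "")[[1]] == "G"
  cs <- c(0, cumsum(isg))
  dens <- function(a, b) (cs[b + 1L] - cs[a + 1L]) / (b - a)  # [a, b) 0-based
  starts <- 0:(n - window)
  wd <- vapply(starts, function(a) dens(a, a + window), numeric(1))
  best <- which.max(wd)   # leftmost on ties
  if (wd[best] < min_density) {
    return(structure(list(region_span = c(0L, 0L), region_size = 0L,
                          gly_fraction = 0, region_seq = "",
                          repetitive_tetrapeptide_count = 0L),
                     class = "isoamp_grich"))
  }
  lo <- starts[best]; hi <- starts[best] + window
  repeat {
    grew <- FALSE
    a <- max(0L, lo - window)
    if (a < lo && dens(a, lo) >= min_density) { lo <- a; grew <- TRUE }
    b <- min(n, hi + window)
    if (b > hi && dens(hi, b) >= min_density) { hi <- b; grew <- TRUE }
    if (!grew) break
  }
  region <- substr(seq, lo + 1L, hi)
  structure(list(region_span = c(lo, hi), region_size = hi - lo,
                 gly_fraction = dens(lo, hi), region_seq = region,
                 repetitive_tetrapeptide_count =
                   count_repetitive_tetrapeptides(region)),
            class = "isoamp_grich")
}

#' Count repeated tetrapeptides in a glycine-rich region
#'
#' A tetrapeptide is "repetitive" when its total (overlapping) occurrence
#' count in the region is at least two. The region is scanned left to right
#' without overlap; every scanned tetrapeptide that is repetitive is
#' counted, and the total count is returned.
#'
#' @param region Peptide substring (a region of length < 4 counts 0).
#' @return Integer count of repetitive tetrapeptide occurrences.
#' @export
count_repetitive_tetrapeptides <- function(region) {
  n <- nchar(region)
  if (n < 4L) return(0L)
  all_tetra <- substring(region, 1:(n - 3L), 4:n)       # overlapping
  occ <- table(all_tetra)
  count <- 0L
  i <- 1L
  while (i <= n - 3L) {
    t <- substr(region, i, i + 3L)
    if (occ[[t]] >= 2L) { count <- count + 1L; i <- i + 4L }
    else i <- i + 1L
  }
  count
}

#' Classify a crustin under the two published typing schemes
#'
#' Under the G-rich-region scheme (Vargas-Albores and Martinez-Porchas) a
#' crustin is type II when its glycine-rich region is at least 100 residues
#' long, at least 20% glycine and carries at least 3 repeated
#' tetrapeptides; otherwise type I. Under the domain-organization scheme
#' (Tassanakajon and colleagues) a crustin with two or more WAP windows is
#' "multi-WAP"; one whose qualifying G-rich region precedes the WAP domain
#' is type II; otherwise type I.
#'
#' @param seq Mature crustin peptide.
#' @param ann The crustin's `isoamp_annotation` from [validate_wap()]
#'   (`family` must be `"crustin"`).
#' @param min_region,min_gly,min_repeats Type II thresholds (defaults 100
#'   residues, 0.20, 3).
#' @return A list of class `isoamp_crustin_type` with fields `vargas_type`
#'   (`"I"`/`"II"`), `tassanakajon_type` (`"I"`/`"II"`/`"multi-WAP"`) and
#'   `evidence` (the `isoamp_grich` stats plus the WAP window count).
#' @export
classify_crustin <- function(seq, ann, min_region = 100L, min_gly = 0.20,
                             min_repeats = 3L) {
  if (!inherits(ann, "isoamp_annotation") || ann$family != "crustin") {
    stop("classify_crustin requires a crustin annotation")
  }
  gr <- if (nchar(seq) >= 20L) detect_grich_region(seq) else
    structure(list(region_span = c(0L, 0L), region_size = 0L,
                   gly_fraction = 0, region_seq = "",
                   repetitive_tetrapeptide_count = 0L),
              class = "isoamp_grich")
  grich_ok <- gr$region_size >= min_region && gr$gly_fraction >= min_gly &&
    gr$repetitive_tetrapeptide_count >= min_repeats
  vargas <- if (grich_ok) "II" else "I"
  n_wap <- as.integer(ann$checks[["wap_count"]])
  tass <- if (n_wap >= 2L) "multi-WAP"
          else if (grich_ok && gr$region_span[1] < ann$domain_span[1]) "II"
          else "I"
  structure(list(vargas_type = vargas, tassanakajon_type = tass,
                 evidence = list(grich = gr, wap_count = n_wap)),
            class = "isoamp_crustin_type")
}

#' Summarize per-species transcript counts
#'
#' @param per_species_counts Named numeric vector (species -> count).
#' @return A list with `mean`, `sd` (sample, n-1), `min`, `max`, all to one
#'   decimal, plus `n_species` and `sd_defined` (`FALSE` for a single
#'   species, in which case `sd` is reported as 0).
#' @export
family_summary <- function(per_species_counts) {
  x <- as.numeric(per_species_counts)
  stopifnot(length(x) >= 1)
  sd_def <- length(x) > 1L
  list(mean = round_half_up(mean(x), 1),
       sd = if (sd_def) round_half_up(stats::sd(x), 1) else 0,
       min = min(x), max = max(x),
       n_species = length(x), sd_defined = sd_def)
}

# round half away from zero (printed-table convention), as opposed to the
# IEEE banker's rounding of base round()
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
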