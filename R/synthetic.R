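# Synthetic transcriptome generator: plants AMP precursors (signal peptide +
# family-specific mature peptide) in random UTR background so that every
# pipeline stage can be validated against a known truth table.
#
# Divergence is modelled at the amino-acid level with the family-diagnostic
# residues (the ALF cysteine pair, the WAP cysteines, the signal anchor
# residues) held invariant -- an explicit model of the purifying selection
# that makes those residues usable as diagnostics in real data -- and the
# mutated precursor is then reverse-translated with uniform synonymous
# codons, which also keeps planted reading frames free of nonsense codons.

# 19-residue A/F-rich signal peptide with an A-X-A cleavage motif
SIGNAL_TEMPLATE <- "MKFAALVALLAVFAAFASA"
SIGNAL_PROTECTED <- c(1L, 17L, 19L)   # Met start, -3 and -1 anchors

# mature templates; ALF and crustin are synthetic constructions to the
# family rules, the armadillidin is the A. vulgare armadillidin H mature
ARMADILLIDIN_MATURE <-
  "GHLGRPYIGGGGGFNRGGGFHRGGGFHRGGGFHSGGGFHRGGGFHSGGSFGYR"
ALF_MATURE <- paste0(
  "QWYKLVVGLVAGALLTVFAAPSIIG",                      # hydrophobic N-terminus
  "EAVC", "KTRGWEAHKSYSGRLGNPRVRRSG", "C",          # Cys pair framing loop
  "PGYTLRPGIKATVSEYVRSGVDVNRAWQSHASNGLVSRSDAATWLSKFA")
WAP_DOMAIN <- "CPNVRGQCLMSCSSDESCPGGYKCCSNGGCGHVCMAPCFKEPCGRTCSQVC"
CRUSTIN_I_MATURE <- paste0(
  "QTYHPPRVPSMVRPHAQYVAPNEWKSTFNAPSVSRPGYLP", WAP_DOMAIN)
CRUSTIN_II_GRICH <- strrep("GYRGNSGGFGKAQGVPGGFGRNSVPG", 5)
CRUSTIN_II_MATURE <- paste0(CRUSTIN_II_GRICH, WAP_DOMAIN)

family_template <- function(family, variant = 1L) {
  mature <- switch(family,
    armadillidin = ARMADILLIDIN_MATURE,
    alf = ALF_MATURE,
    crustin = if (variant %% 2L == 0L) CRUSTIN_II_MATURE else CRUSTIN_I_MATURE,
    stop("unknown family: ", family))
  nsig <- nchar(SIGNAL_TEMPLATE)
  protect <- SIGNAL_PROTECTED
  if (family == "alf" || family == "crustin") {
    protect <- c(protect, nsig + cys_positions(mature) + 1L)  # 1-based
  }
  list(precursor = paste0(SIGNAL_TEMPLATE, mature), protect = protect,
       signal_length = nsig)
}

#' Synthetic transcriptome configuration
#'
#' Defaults emulate the mined study system: 21 terrestrial isopod species,
#' one planted armadillidin, ALF and crustin precursor per species at 5%
#' residue divergence from the family templates, embedded in random UTR
#' background among ORF-poor background transcripts.
#'
#' @param n_species Number of species.
#' @param transcripts_per_species Total transcripts per species (planted +
#'   background).
#' @param planted Named counts per species, names among `armadillidin`,
#'   `alf`, `crustin`.
#' @param mutation_rate Per-residue substitution probability applied to
#'   each planted precursor.
#' @param utr_length_range Min/max UTR length in nucleotides.
#' @param seed Integer seed; the whole generation is deterministic given it.
#' @return A list of class `isoamp_synth_config`.
#' @export
synth_config <- function(n_species = 21L, transcripts_per_species = 10L,
                         planted = c(armadillidin = 1L, alf = 1L,
                                     crustin = 1L),
                         mutation_rate = 0.05,
                         utr_length_range = c(30L, 150L), seed = 1L) {
  stopifnot(n_species >= 1L, mutation_rate >= 0, mutation_rate <= 1,
            all(planted >= 0L), transcripts_per_species >= sum(planted),
            length(utr_length_range) == 2L,
            utr_length_range[1] >= 3L,
            utr_length_range[1] <= utr_length_range[2])
  structure(list(n_species = as.integer(n_species),
                 transcripts_per_species = as.integer(transcripts_per_species),
                 planted = planted, mutation_rate = mutation_rate,
                 utr_length_range = as.integer(utr_length_range),
                 seed = as.integer(seed)),
            class = "isoamp_synth_config")
}

# mutation without touching the RNG state management (used inside the
# generator, which seeds once)
mutate_chars <- function(seq, rate, alphabet, protect = integer(0)) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    alt <- setdiff(alphabet, chars[i])
    chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

#' Mutate a sequence by independent point substitutions
#'
#' Each position is substituted, independently with probability `rate`, by
#' a letter drawn uniformly from the other letters of the alphabet. Length
#' is preserved and the result is deterministic given `seed`.
#'
#' @param seq DNA or peptide string.
#' @param rate Substitution probability per position, in `[0, 1]`.
#' @param seed Integer seed.
#' @param alphabet Substitution alphabet; inferred from the sequence when
#'   `NULL` (`ACGT` if the letters are nucleotides, the 20 standard amino
#'   acids otherwise).
#' @param protect 1-based positions never substituted.
#' @return The mutated string.
#' @export
mutate_sequence <- function(seq, rate, seed, alphabet = NULL,
                            protect = integer(0)) {
  stopifnot(rate >= 0, rate <= 1)
  if (is.null(alphabet)) {
    letters_in <- unique(strsplit(seq, "")[[1]])
    alphabet <- if (all(letters_in %in% DNA_LETTERS)) c("A", "C", "G", "T")
                else AA_LETTERS
  }
  with_seed(seed, mutate_chars(seq, rate, alphabet, protect))
}

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop codons in all three frames of both strands: "TAA" at offsets 0,1,2
# (forward frames) followed by "TTA" at offsets 0,1,2 (read as TAA in every
# reverse frame). Placed between UTR and coding sequence it terminates any
# reading-frame run crossing the junction within a few codons.
STOP_CASSETTE <- "TAATAATAATTATTATTA"

# uniform synonymous codon choice
reverse_translate <- function(peptide) {
  chars <- strsplit(peptide, "")[[1]]
  codons_of <- split(names(GENETIC_CODE_1), GENETIC_CODE_1)
  paste(vapply(chars, function(a) {
    cods <- codons_of[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Generate a synthetic transcriptome with planted AMP precursors
#'
#' Each planted AMP is built from its family template (see the package
#' vignette), mutated at the configured residue divergence with diagnostic
#' residues held invariant, reverse-translated with uniform synonymous
#' codons, framed by an in-frame upstream stop, a start codon context and a
#' stop codon, flanked by random UTRs and placed on a random strand. UTRs
#' are resampled until the precursor is the unique longest ORF of its
#' transcript, so that longest-ORF translation provably recovers it.
#' Background transcripts are random, ORF-poor sequence.
#'
#' @param cfg A [synth_config()].
#' @return A list with `transcripts` (record `data.frame`) and `truth`
#'   (`data.frame`: `species`, `transcript_id`, `family`, `strand`,
#'   `precursor_start`, `precursor_end`, `signal_start`, `signal_end`
#'   (0-based half-open, forward strand), `precursor_seq`, `mature_seq`).
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "isoamp_synth_config"))
  with_seed(cfg$seed, {
    recs <- list(); truths <- list()
    for (sp in seq_len(cfg$n_species)) {
      species <- sprintf("sp%02d", sp)
      t_idx <- 0L
      for (family in names(cfg$planted)) {
        for (copy in seq_len(cfg$planted[[family]])) {
          t_idx <- t_idx + 1L
          tid <- sprintf("%s_t%02d", species, t_idx)
          tmpl <- family_template(family, variant = sp)
          prec <- mutate_chars(tmpl$precursor, cfg$mutation_rate,
                               AA_LETTERS, tmpl$protect)
          strand <- sample(c("+", "-"), 1L)
          # resample codons and UTRs until the precursor is the unique
          # longest ORF of the transcript (competing stop-free runs in
          # shifted frames depend on the synonymous codon choices)
          for (try in 1:100) {
            cds <- reverse_translate(prec)
            stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
            u5 <- stats::runif(1, cfg$utr_length_range[1],
                               cfg$utr_length_range[2])
            u3 <- stats::runif(1, cfg$utr_length_range[1],
                               cfg$utr_length_range[2])
            utr5 <- paste0(random_dna(floor(u5) - 3L), STOP_CASSETTE, "TAA")
            utr3 <- paste0(STOP_CASSETTE, random_dna(floor(u3)))
            fwd <- paste0(utr5, cds, stop_codon, utr3)
            tx <- if (strand == "+") fwd else revcomp_dna(fwd)
            long <- find_orfs(list(id = tid, seq = tx),
                              min_aa = nchar(prec))
            if (nrow(long) == 1L && long$peptide[1] == prec) break
          }
          cs <- nchar(utr5); ce <- cs + nchar(cds)   # forward coords of fwd
          L <- nchar(fwd)
          if (strand == "+") {
            p_span <- c(cs, ce)
            s_span <- c(cs, cs + 3L * tmpl$signal_length)
          } else {
            p_span <- c(L - ce, L - cs)
            s_span <- c(L - (cs + 3L * tmpl$signal_length), L - cs)
          }
          recs[[tid]] <- data.frame(id = tid, seq = tx)
          truths[[tid]] <- data.frame(
            species = species, transcript_id = tid, family = family,
            strand = strand,
            precursor_start = p_span[1], precursor_end = p_span[2],
            signal_start = s_span[1], signal_end = s_span[2],
            precursor_seq = prec,
            mature_seq = substr(prec, tmpl$signal_length + 1L, nchar(prec)))
        }
      }
      n_bg <- cfg$transcripts_per_species - sum(cfg$planted)
      for (b in seq_len(n_bg)) {
        t_idx <- t_idx + 1L
        tid <- sprintf("%s_t%02d", species, t_idx)
        recs[[tid]] <- data.frame(
          id = tid, seq = random_dna(floor(stats::runif(1, 300, 800))))
      }
    }
    transcripts <- if (length(recs)) do.call(rbind, recs) else
      data.frame(id = character(0), seq = character(0))
    rownames(transcripts) <- NULL
    truth <- if (length(truths)) do.call(rbind, truths) else
      data.frame(species = character(0), transcript_id = character(0),
                 family = character(0), strand = character(0),
                 precursor_start = integer(0), precursor_end = integer(0),
                 signal_start = integer(0), signal_end = integer(0),
                 precursor_seq = character(0), mature_seq = character(0))
    rownames(truth) <- NULL
    list(transcripts = transcripts, truth = truth)
  })
}
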