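# Sequence I/O, ORF finding and redundancy collapse.

DNA_LETTERS <- c("A", "C", "G", "T", "N")

#' Read a FASTA file into a record table
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file. Headers are taken
#' up to the first whitespace as record ids; sequences are uppercased and, for
#' DNA, `U` is mapped to `T`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"dna"` (letters `A,C,G,T,N`) or `"protein"` (the 20
#'   standard letters plus `X`).
#' @return A `data.frame` with columns `id` and `seq`, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt"), fa)
#' read_fasta(fa, "dna")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(id = character(0), seq = character(0)))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence before header at line ", first)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(!nzchar(ids))) stop("malformed FASTA: empty record id")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "dna") {
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
    allowed <- DNA_LETTERS
  } else {
    allowed <- c(AA_LETTERS, "X")
  }
  bad <- setdiff(unique(unlist(strsplit(seqs, ""))), allowed)
  if (length(bad) > 0) {
    stop("letter outside ", alphabet, " alphabet: ", bad[1])
  }
  if (any(!nzchar(seqs))) stop("empty sequence for id: ", ids[!nzchar(seqs)][1])
  data.frame(id = unname(ids), seq = unname(seqs))
}

#' Write a record table to FASTA
#'
#' @param records `data.frame` with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# accept a single-row data.frame or a list(id=, seq=)
as_record <- function(rec) {
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- as.list(rec)
  }
  stopifnot(!is.null(rec$id), !is.null(rec$seq))
  rec
}

empty_orfs <- function() {
  data.frame(parent_id = character(0), frame = integer(0),
             start = integer(0), end = integer(0), peptide = character(0))
}

FRAME_ORDER <- c(`1` = 1L, `2` = 2L, `3` = 3L, `-1` = 4L, `-2` = 5L, `-3` = 6L)

# codon lookup over {A,C,G,T,N}^3, built once from the standard genetic
# code; any codon containing N translates to X
codon_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      combos <- expand.grid(DNA_LETTERS, DNA_LETTERS, DNA_LETTERS,
                            stringsAsFactors = FALSE)
      codons <- paste0(combos[[1]], combos[[2]], combos[[3]])
      aa <- GENETIC_CODE_1[codons]
      aa[is.na(aa)] <- "X"
      tab <<- setNames(aa, codons)
    }
    tab
  }
})

translate_dna <- function(seq) {
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n_codon)
  paste(codon_lookup()[substring(seq, starts, starts + 2L)], collapse = "")
}

revcomp_dna <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Find open reading frames in all six frames
#'
#' An ORF is a maximal stop-free codon run (stop-to-stop; contig edges count
#' as boundaries), translated with the standard genetic code. Codons
#' containing `N` translate to `X`.
#'
#' @param rec A nucleotide record (single-row `data.frame` or
#'   `list(id=, seq=)`).
#' @param min_aa Minimum peptide length in residues (>= 1).
#' @return A `data.frame` with columns `parent_id`, `frame` (one of
#'   `+1,+2,+3,-1,-2,-3`), `start`, `end` (0-based half-open nucleotide
#'   coordinates on the forward strand, covering the peptide codons), and
#'   `peptide`, sorted by peptide length descending (ties: frame order
#'   `+1,+2,+3,-1,-2,-3`, then smaller start).
#' @export
find_orfs <- function(rec, min_aa = 1L) {
  stopifnot(min_aa >= 1L)
  rec <- as_record(rec)
  L <- nchar(rec$seq)
  if (L < 3L) return(empty_orfs())
  fwd <- rec$seq
  rev <- revcomp_dna(fwd)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (f in 0:2) {
      n_codon <- (L - f) %/% 3L
      if (n_codon < 1L) next
      pep <- translate_dna(substr(s, f + 1L, f + 3L * n_codon))
      # maximal stop-free runs
      runs <- gregexpr("[^*]+", pep)[[1]]
      if (runs[1] == -1L) next
      lens <- attr(runs, "match.length")
      sel <- lens >= min_aa
      if (!any(sel)) next
      p1 <- as.integer(runs[sel]); lk <- lens[sel]  # 1-based aa starts
      st <- f + 3L * (p1 - 1L)            # 0-based on the scanned strand
      en <- st + 3L * lk
      if (strand == -1L) { tmp <- st; st <- L - en; en <- L - tmp }
      out[[length(out) + 1L]] <- data.frame(
        parent_id = rec$id, frame = strand * (f + 1L),
        start = st, end = en,
        peptide = substring(pep, p1, p1 + lk - 1L))
    }
  }
  if (length(out) == 0L) return(empty_orfs())
  orfs <- do.call(rbind, out)
  ord <- order(-nchar(orfs$peptide), FRAME_ORDER[as.character(orfs$frame)],
               orfs$start)
  orfs <- orfs[ord, , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Translate the longest ORF of a transcript
#'
#' Ties are broken by frame order `+1,+2,+3,-1,-2,-3`, then by smaller start
#' coordinate.
#'
#' @inheritParams find_orfs
#' @return A single-row `data.frame` with columns `id` (parent id suffixed
#'   `_orf`), `seq`, `parent_id`, `frame`, `start`, `end`; or a zero-row
#'   `data.frame` when the transcript has no ORF (explicit "no ORF" result).
#' @export
longest_orf_peptide <- function(rec) {
  orfs <- find_orfs(rec, min_aa = 1L)
  if (nrow(orfs) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      parent_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0)))
  }
  top <- orfs[1L, ]
  data.frame(id = paste0(top$parent_id, "_orf"), seq = top$peptide,
             parent_id = top$parent_id, frame = top$frame,
             start = top$start, end = top$end)
}

# cheap k-mer screen before the quadratic alignment: sequences at >= 95%
# identity over a few hundred nucleotides share hundreds of 11-mers,
# unrelated random ones a handful at most
shares_kmer <- function(a, b, k = 11L, min_shared = 5L) {
  na <- nchar(a); nb <- nchar(b)
  if (min(na, nb) < k + 20L) return(TRUE)  # short: just align
  ka <- unique(substring(a, 1:(na - k + 1L), k:na))
  kb <- unique(substring(b, 1:(nb - k + 1L), k:nb))
  # low-complexity sequences may hold fewer distinct k-mers than the cutoff
  length(intersect(ka, kb)) >= min(min_shared, length(ka), length(kb))
}

#' Collapse redundant contigs at a nucleotide identity threshold
#'
#' Greedy incremental clustering in the spirit of CD-HIT: records are sorted
#' by length (descending) and each joins the first existing cluster whose
#' representative aligns to it (global alignment) with identity at or above
#' the threshold; otherwise it founds a new cluster. Identity is matches
#' divided by the length of the shorter sequence; `N` never counts as a
#' match.
#'
#' @param records `data.frame` with columns `id` and `seq` (DNA).
#' @param identity_threshold Fraction in (0, 1]; default 0.95.
#' @return A `data.frame` with one row per input record: `representative_id`,
#'   `member_id`, `identity` (1 for representatives against themselves).
#' @export
collapse_redundant <- function(records, identity_threshold = 0.95) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(records) == 0L) {
    return(data.frame(representative_id = character(0),
                      member_id = character(0), identity = numeric(0)))
  }
  scheme <- dna_scoring_scheme()
  ord <- order(-nchar(records$seq))
  recs <- records[ord, , drop = FALSE]
  rep_id <- character(0); rep_seq <- character(0)
  rows <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    placed <- FALSE
    for (ci in seq_along(rep_id)) {
      if (!shares_kmer(rep_seq[ci], recs$seq[i])) next
      idn <- global_identity(rep_seq[ci], recs$seq[i], scheme)
      if (idn >= identity_threshold) {
        rows[[i]] <- data.frame(representative_id = rep_id[ci],
                                member_id = recs$id[i], identity = idn)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_id <- c(rep_id, recs$id[i])
      rep_seq <- c(rep_seq, recs$seq[i])
      rows[[i]] <- data.frame(representative_id = recs$id[i],
                              member_id = recs$id[i], identity = 1)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# global-alignment identity with matches / shorter-length denominator;
# ambiguous letters (N/X) never count as matches
global_identity <- function(a, b, scheme) {
  aln <- global_align(a, b, scheme)
  ca <- strsplit(aln$rows[1], "")[[1]]
  cb <- strsplit(aln$rows[2], "")[[1]]
  matches <- sum(ca == cb & ca != "-" & ca != "N" & ca != "X")
  matches / min(nchar(a), nchar(b))
}
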