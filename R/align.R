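# Exhaustive pairwise alignment and homology search with Karlin-Altschul
# statistics. The dynamic programming core lives in src/align.cpp; ties in
# the traceback are resolved diagonal > up > left so results are
# reproducible.

.pkg_cache <- new.env(parent = emptyenv())

get_submatrix <- function(name) {
  key <- paste0("submat_", name)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || is.null(e[[name]])) stop("unknown substitution matrix: ", name)
  m <- e[[name]]
  .pkg_cache[[key]] <- m
  m
}

#' Protein scoring scheme for alignment and E-value statistics
#'
#' Defaults are the classical gapped BLOSUM62/11/1 parameters with their
#' published Karlin-Altschul constants (lambda = 0.267, K = 0.041).
#'
#' @param matrix Substitution matrix name (as shipped with Biostrings).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param karlin_lambda,karlin_K Karlin-Altschul parameters for the E-value.
#' @return A list of class `isoamp_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           karlin_lambda = 0.267, karlin_K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            karlin_lambda > 0, karlin_K > 0)
  S <- get_submatrix(matrix)
  structure(list(matrix_name = matrix, matrix = S,
                 letters = rownames(S),
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K),
            class = "isoamp_scheme")
}

#' Nucleotide scoring scheme for the redundancy collapse
#'
#' Simple match/mismatch scoring; `N` scores as a mismatch against
#' everything, including itself.
#'
#' @param match,mismatch Match reward and mismatch penalty.
#' @param gap_open,gap_extend Gap penalties (see [scoring_scheme()]).
#' @return A list of class `isoamp_scheme`.
#' @export
dna_scoring_scheme <- function(match = 5, mismatch = -4, gap_open = 10,
                               gap_extend = 1) {
  letters <- DNA_LETTERS
  S <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(S) <- match
  S["N", "N"] <- mismatch
  structure(list(matrix_name = "dna", matrix = S, letters = letters,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = NA_real_, karlin_K = NA_real_),
            class = "isoamp_scheme")
}

encode_seq <- function(seq, scheme) {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, scheme$letters)
  if (anyNA(codes)) {
    stop("letter outside alignment alphabet: ", chars[is.na(codes)][1])
  }
  codes - 1L
}

alignment_identity <- function(aligned_a, aligned_b) {
  if (!nzchar(aligned_a)) return(0)
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  sum(ca == cb & ca != "-" & ca != "X" & ca != "N") / length(ca)
}

#' Karlin-Altschul E-value of a raw local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param raw_score Raw alignment score.
#' @param m Query length in residues.
#' @param n Database size in residues.
#' @param scheme A [scoring_scheme()].
#' @return The expected number of chance hits at this score or better.
#' @export
evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(m >= 1, n >= 1)
  scheme$karlin_K * m * n * exp(-scheme$karlin_lambda * raw_score)
}

#' Bit score of a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`.
#'
#' @inheritParams evalue
#' @return Bit score.
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$karlin_lambda * raw_score - log(scheme$karlin_K)) / log(2)
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' Returns the optimal score and one optimal traceback (tie-break: diagonal,
#' then up, then left). The score of two unrelated sequences is never
#' negative; when no positive-scoring alignment exists the aligned strings
#' are empty.
#'
#' @param query,subject Peptide strings (or DNA with a DNA scheme).
#' @param scheme A [scoring_scheme()] or [dna_scoring_scheme()].
#' @return A list of class `isoamp_alignment` with fields `raw_score`,
#'   `bit_score`, `evalue` (computed with `m = nchar(query)`,
#'   `n = nchar(subject)`), `identity_fraction` (identical columns /
#'   alignment columns), `query_span` and `subject_span` (0-based half-open),
#'   `aligned_query`, `aligned_subject`.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme()) {
  stopifnot(nzchar(query), nzchar(subject))
  r <- .cpp_align_pair(encode_seq(query, scheme), encode_seq(subject, scheme),
                       scheme$matrix, scheme$gap_open, scheme$gap_extend,
                       TRUE, scheme$letters)
  ev <- if (is.na(scheme$karlin_lambda)) NA_real_ else
    evalue(r$score, nchar(query), nchar(subject), scheme)
  bs <- if (is.na(scheme$karlin_lambda)) NA_real_ else
    bit_score(r$score, scheme)
  structure(list(
    raw_score = r$score, bit_score = bs, evalue = ev,
    identity_fraction = alignment_identity(r$aligned_a, r$aligned_b),
    query_span = c(r$a_start, r$a_end),
    subject_span = c(r$b_start, r$b_end),
    aligned_query = r$aligned_a, aligned_subject = r$aligned_b),
    class = "isoamp_alignment")
}

#' Optimal global (Needleman-Wunsch) alignment with affine gaps
#'
#' End gaps are penalized; ties in the traceback are resolved as in
#' [local_align()].
#'
#' @param a,b Sequences to align.
#' @param scheme A [scoring_scheme()] or [dna_scoring_scheme()].
#' @return A two-row multiple alignment (class `isoamp_msa`; see
#'   [progressive_msa()]) with an additional `score` field.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  stopifnot(nzchar(a), nzchar(b))
  r <- .cpp_align_pair(encode_seq(a, scheme), encode_seq(b, scheme),
                       scheme$matrix, scheme$gap_open, scheme$gap_extend,
                       FALSE, scheme$letters)
  new_msa(ids = c("a", "b"), rows = c(r$aligned_a, r$aligned_b),
          score = r$score)
}

#' Exhaustive homology search of peptide queries against a peptide database
#'
#' Every query x subject pair is aligned by Smith-Waterman; hits are filtered
#' by Karlin-Altschul E-value with the database size `n` set to the total
#' residue count of the database.
#'
#' @param queries,database Record `data.frame`s with columns `id`, `seq`.
#' @param scheme A [scoring_scheme()].
#' @param evalue_max Keep hits with `E <= evalue_max` (default `1e-10`).
#' @return A `data.frame` of hits sorted by ascending E-value (ties: higher
#'   raw score, then query and subject id) with columns `query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `evalue`, `identity_fraction`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`,
#'   `aligned_query`, `aligned_subject` (spans 0-based half-open).
#' @export
homology_search <- function(queries, database, scheme = scoring_scheme(),
                            evalue_max = 1e-10) {
  stopifnot(nrow(database) > 0)
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      raw_score = numeric(0), bit_score = numeric(0),
                      evalue = numeric(0), identity_fraction = numeric(0),
                      query_start = integer(0), query_end = integer(0),
                      subject_start = integer(0), subject_end = integer(0),
                      aligned_query = character(0),
                      aligned_subject = character(0))
  if (nrow(queries) == 0L) return(empty)
  n_db <- sum(nchar(database$seq))
  subj_codes <- lapply(database$seq, encode_seq, scheme = scheme)
  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    qcode <- encode_seq(queries$seq[qi], scheme)
    scores <- .cpp_local_scores(qcode, subj_codes, scheme$matrix,
                                scheme$gap_open, scheme$gap_extend)
    evs <- evalue(scores, nchar(queries$seq[qi]), n_db, scheme)
    for (si in which(evs <= evalue_max)) {
      aln <- local_align(queries$seq[qi], database$seq[si], scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = queries$id[qi], subject_id = database$id[si],
        raw_score = aln$raw_score, bit_score = aln$bit_score,
        evalue = evalue(aln$raw_score, nchar(queries$seq[qi]), n_db, scheme),
        identity_fraction = aln$identity_fraction,
        query_start = aln$query_span[1], query_end = aln$query_span[2],
        subject_start = aln$subject_span[1], subject_end = aln$subject_span[2],
        aligned_query = aln$aligned_query,
        aligned_subject = aln$aligned_subject)
    }
  }
  if (length(rows) == 0L) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$evalue, -hits$raw_score, hits$query_id,
                     hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Reciprocal-best confirmation of homology hits
#'
#' A hit (query -> subject) is retained if and only if aligning the subject
#' back against the full family reference set returns, as best hit, a
#' reference belonging to the same family as the query.
#'
#' @param hits Hit table from [homology_search()].
#' @param query_set Reference records `data.frame` with columns `id`,
#'   `family`, `seq` (must contain every query of `hits`).
#' @param database Record `data.frame` the subjects came from.
#' @param scheme A [scoring_scheme()].
#' @return The confirmed subset of `hits`.
#' @export
reciprocal_confirm <- function(hits, query_set, database,
                               scheme = scoring_scheme()) {
  if (nrow(hits) == 0L) return(hits)
  stopifnot(all(hits$query_id %in% query_set$id))
  fam_of_query <- setNames(query_set$family, query_set$id)
  ref_codes <- lapply(query_set$seq, encode_seq, scheme = scheme)
  subj_ids <- unique(hits$subject_id)
  best_fam <- character(0)
  for (sid in subj_ids) {
    sseq <- database$seq[match(sid, database$id)]
    scores <- .cpp_local_scores(encode_seq(sseq, scheme), ref_codes,
                                scheme$matrix, scheme$gap_open,
                                scheme$gap_extend)
    best_fam[sid] <- query_set$family[which.max(scores)]
  }
  keep <- fam_of_query[hits$query_id] == best_fam[hits$subject_id]
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Format hits in BLAST outfmt-6 column order
#'
#' @param hits Hit table from [homology_search()].
#' @return A `data.frame` with columns `qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore`
#'   (coordinates 0-based half-open).
#' @export
hits_outfmt6 <- function(hits) {
  ncol_aln <- nchar(hits$aligned_query)
  gaps_q <- vapply(gregexpr("-+", hits$aligned_query),
                   function(g) if (g[1] == -1L) 0L else length(g), integer(1))
  gaps_s <- vapply(gregexpr("-+", hits$aligned_subject),
                   function(g) if (g[1] == -1L) 0L else length(g), integer(1))
  nident <- round(hits$identity_fraction * ncol_aln)
  ngapcol <- (ncol_aln - (hits$query_end - hits$query_start)) +
    (ncol_aln - (hits$subject_end - hits$subject_start))
  data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
             pident = round(100 * hits$identity_fraction, 2),
             length = ncol_aln,
             mismatch = ncol_aln - ngapcol - nident,
             gapopen = gaps_q + gaps_s,
             qstart = hits$query_start, qend = hits$query_end,
             sstart = hits$subject_start, send = hits$subject_end,
             evalue = hits$evalue, bitscore = round(hits$bit_score, 1))
}
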