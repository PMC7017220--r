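# Progressive multiple alignment, block trimming and column consensus.

#' Construct a multiple alignment object
#'
#' @param ids Character vector of sequence ids.
#' @param rows Equal-length gapped strings (one per id).
#' @param score Optional alignment score (pairwise case).
#' @return A list of class `isoamp_msa` with fields `ids`, `rows`,
#'   `column_count` and optionally `score`.
#' @export
new_msa <- function(ids, rows, score = NULL) {
  stopifnot(length(ids) == length(rows))
  if (length(rows) > 0) stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(ids = ids, rows = rows,
                 column_count = if (length(rows)) nchar(rows[1]) else 0L,
                 score = score),
            class = "isoamp_msa")
}

#' @export
print.isoamp_msa <- function(x, ...) {
  cat("isoamp multiple alignment:", length(x$rows), "sequences x",
      x$column_count, "columns\n")
  w <- max(nchar(x$ids), 0)
  for (i in seq_along(x$rows)) {
    cat(formatC(x$ids[i], width = w), " ",
        substr(x$rows[i], 1, 60),
        if (x$column_count > 60) "..." else "", "\n", sep = "")
  }
  invisible(x)
}

msa_matrix <- function(msa) {
  if (length(msa$rows) == 0L) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  do.call(rbind, strsplit(msa$rows, ""))
}

ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# column composition (letters x columns frequency matrix, gaps excluded from
# the rows but counted in the denominator)
profile_composition <- function(mat, letters) {
  comp <- matrix(0, nrow = length(letters), ncol = ncol(mat),
                 dimnames = list(letters, NULL))
  nr <- nrow(mat)
  for (j in seq_len(ncol(mat))) {
    tab <- table(factor(mat[, j], levels = letters))
    comp[, j] <- as.numeric(tab) / nr
  }
  comp
}

# profile-to-profile global alignment with affine gaps ("once a gap, always
# a gap"); returns the merged character matrix. Gap penalties are scaled by
# the non-gap fraction of the column being aligned against a gap
# (CLUSTAL-style position-specific penalties), so that new gaps consolidate
# in columns that already hold gaps instead of scattering through runs of
# identical residues.
profile_align <- function(A, B, scheme) {
  letters <- scheme$letters
  S <- scheme$matrix
  CA <- profile_composition(A, letters)
  CB <- profile_composition(B, letters)
  score <- t(CA) %*% S %*% CB      # column-pair expected substitution score
  wA <- colMeans(A != "-")         # non-gap weight per column
  wB <- colMeans(B != "-")
  n <- ncol(A); m <- ncol(B)
  open <- scheme$gap_open + scheme$gap_extend
  ext <- scheme$gap_extend
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  tbM <- matrix(0L, n + 1, m + 1); tbX <- tbM; tbY <- tbM
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    Ix[i, 1] <- Ix[max(i - 1, 1), 1] -
      (if (i == 2) open else ext) * wA[i - 1]
    if (i == 2) Ix[2, 1] <- -open * wA[1]
    tbX[i, 1] <- if (i == 2) 0L else 1L
  }
  for (j in 2:(m + 1)) {
    Iy[1, j] <- (if (j == 2) 0 else Iy[1, j - 1]) -
      (if (j == 2) open else ext) * wB[j - 1]
    tbY[1, j] <- if (j == 2) 0L else 2L
  }
  # on (numerical) ties entering the match state, prefer closing a gap over
  # the diagonal: this left-aligns runs of identical residues across rows,
  # keeping the register of repeat units (G-runs) consistent between merges
  pick_gap_first <- function(cand) {
    ord <- c(2L, 3L, 1L)
    ord[which(cand[ord] >= max(cand) - 1e-9)][1]
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- score[i - 1, j - 1]
      cand <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      k <- pick_gap_first(cand)
      M[i, j] <- cand[k] + s; tbM[i, j] <- k - 1L
      # consume column i-1 of A against a gap in B: cost scaled by how
      # occupied that A column is
      cand <- c(M[i - 1, j] - open * wA[i - 1],
                Ix[i - 1, j] - ext * wA[i - 1],
                Iy[i - 1, j] - open * wA[i - 1])
      k <- which.max(cand)
      Ix[i, j] <- cand[k]; tbX[i, j] <- k - 1L
      cand <- c(M[i, j - 1] - open * wB[j - 1],
                Ix[i, j - 1] - open * wB[j - 1],
                Iy[i, j - 1] - ext * wB[j - 1])
      k <- which.max(cand)
      Iy[i, j] <- cand[k]; tbY[i, j] <- k - 1L
    }
  }
  cand <- c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  state <- which.max(cand) - 1L
  i <- n; j <- m
  steps <- character(0)
  while (i > 0 || j > 0) {
    if (state == 0L) {
      from <- tbM[i + 1, j + 1]; steps <- c("D", steps); i <- i - 1; j <- j - 1
    } else if (state == 1L) {
      from <- tbX[i + 1, j + 1]; steps <- c("U", steps); i <- i - 1
    } else {
      from <- tbY[i + 1, j + 1]; steps <- c("L", steps); j <- j - 1
    }
    state <- from
  }
  out <- matrix("-", nrow = nrow(A) + nrow(B), ncol = length(steps))
  ia <- 1L; ib <- 1L
  ra <- seq_len(nrow(A)); rb <- nrow(A) + seq_len(nrow(B))
  for (k in seq_along(steps)) {
    if (steps[k] != "L") { out[ra, k] <- A[, ia]; ia <- ia + 1L }
    if (steps[k] != "U") { out[rb, k] <- B[, ib]; ib <- ib + 1L }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Pairwise global alignments give identity distances; a UPGMA guide tree
#' orders the merges; profiles are merged profile-to-profile so that a gap,
#' once introduced, is never removed.
#'
#' @param seqs Record `data.frame` with columns `id`, `seq` (>= 1 sequence).
#' @param scheme A [scoring_scheme()].
#' @return An `isoamp_msa`; ungapping row i reproduces input sequence i
#'   (rows are reported in input order).
#' @export
progressive_msa <- function(seqs, scheme = scoring_scheme()) {
  n <- nrow(seqs)
  stopifnot(n >= 1)
  if (n == 1L) return(new_msa(seqs$id, seqs$seq))
  ids <- seqs$id
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- global_align(seqs$seq[i], seqs$seq[j], scheme)
      idn <- alignment_identity(aln$rows[1], aln$rows[2])
      d[i, j] <- d[j, i] <- 1 - idn
    }
  }
  if (n == 2L) {
    aln <- global_align(seqs$seq[1], seqs$seq[2], scheme)
    return(new_msa(ids, aln$rows))
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  profiles <- list()   # by merge step
  members <- list()
  for (k in seq_len(nrow(tree$merge))) {
    pick <- function(x) {
      if (x < 0) {
        list(mat = matrix(strsplit(seqs$seq[-x], "")[[1]], nrow = 1),
             idx = -x)
      } else {
        list(mat = profiles[[x]], idx = members[[x]])
      }
    }
    a <- pick(tree$merge[k, 1]); b <- pick(tree$merge[k, 2])
    profiles[[k]] <- profile_align(a$mat, b$mat, scheme)
    members[[k]] <- c(a$idx, b$idx)
  }
  final <- profiles[[nrow(tree$merge)]]
  ord <- order(members[[nrow(tree$merge)]])
  rows <- apply(final[ord, , drop = FALSE], 1, paste, collapse = "")
  new_msa(ids, rows)
}

#' Trim ambiguously aligned regions from a multiple alignment
#'
#' Columns whose gap fraction exceeds `max_gap_fraction` are dropped, then
#' retained runs of consecutive columns shorter than `min_block` are dropped
#' as well (a permissive, GBLOCKS-style block filter). Row order is
#' preserved. The operation is idempotent.
#'
#' @param msa An `isoamp_msa`.
#' @param max_gap_fraction Maximum tolerated per-column gap fraction.
#' @param min_block Minimum length of a retained column run.
#' @return The trimmed `isoamp_msa`; when every column is dropped an empty
#'   alignment is returned with a warning.
#' @export
trim_blocks <- function(msa, max_gap_fraction = 0.5, min_block = 5L) {
  mat <- msa_matrix(msa)
  if (ncol(mat) == 0L) return(msa)
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_fraction
  # drop kept runs shorter than min_block
  r <- rle(keep)
  r$values[r$values & r$lengths < min_block] <- FALSE
  keep <- inverse.rle(r)
  if (!any(keep)) {
    warning("all columns removed by trimming")
    return(new_msa(msa$ids, rep("", length(msa$ids))))
  }
  mat <- mat[, keep, drop = FALSE]
  new_msa(msa$ids, apply(mat, 1, paste, collapse = ""))
}

#' Physico-chemical column consensus of a multiple alignment
#'
#' Per column, residues are grouped into physico-chemical classes
#' (aliphatic AVLIM, aromatic FWY, hydroxyl ST, acidic DE, amide NQ, basic
#' KRH, and C, G, P as singletons). If the modal residue reaches the
#' threshold it is emitted; otherwise, if the modal class reaches the
#' threshold, the modal residue of that class is emitted; otherwise `-`.
#' Gaps count against conservation.
#'
#' @param msa An `isoamp_msa` with >= 2 rows.
#' @param similarity_threshold Fraction of rows that must agree (default
#'   0.70).
#' @return A list of class `isoamp_consensus` with fields `consensus`
#'   (string) and `column_conservation` (modal class frequency per column).
#' @export
column_consensus <- function(msa, similarity_threshold = 0.70) {
  stopifnot(length(msa$rows) >= 2)
  mat <- msa_matrix(msa)
  nr <- nrow(mat)
  cons <- character(ncol(mat))
  conserv <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    counts <- table(col[col %in% AA_LETTERS])
    if (length(counts) == 0L) { cons[j] <- "-"; conserv[j] <- 0; next }
    counts <- counts[order(-counts, names(counts))]
    res_freq <- counts[1] / nr
    cls <- residue_class_of(names(counts))
    cls_freq <- tapply(as.numeric(counts), cls, sum) / nr
    cls_freq <- cls_freq[order(-cls_freq, names(cls_freq))]
    conserv[j] <- as.numeric(cls_freq[1])
    if (res_freq >= similarity_threshold) {
      cons[j] <- names(counts)[1]
    } else if (cls_freq[1] >= similarity_threshold) {
      in_class <- counts[cls == names(cls_freq)[1]]
      cons[j] <- names(in_class)[1]
    } else {
      cons[j] <- "-"
    }
  }
  structure(list(consensus = paste(cons, collapse = ""),
                 column_conservation = conserv),
            class = "isoamp_consensus")
}

#' Write an alignment to aligned FASTA
#'
#' @param msa An `isoamp_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  write_fasta(data.frame(id = msa$ids, seq = msa$rows), path)
}
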