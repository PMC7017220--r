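# Independent oracles used to validate the package implementations. These
# are deliberately written as direct, unoptimized computations that share no
# code with the package.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(AA20, n, TRUE), collapse = "")
random_dna_str <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                    collapse = "")

# quadratic-space three-state affine DP, scores only; gap of length k costs
# open + k * ext; local mode clamps at zero and takes the best cell
ref_align_score <- function(a, b, S, open, ext, local) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
    for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- S[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      if (local) M[i, j] <- max(0, M[i, j])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                     Y[i - 1, j] - open - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
      if (local && M[i, j] > best) best <- M[i, j]
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# enumeration oracle for glycine runs: walk the characters and collect
# maximal runs of >= 2 G
ref_g_runs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  runs <- list()
  i <- 1
  while (i <= length(ch)) {
    if (ch[i] == "G") {
      j <- i
      while (j < length(ch) && ch[j + 1] == "G") j <- j + 1
      if (j - i + 1 >= 2) {
        runs[[length(runs) + 1]] <- c(start = i - 1, len = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# brute-force six-frame ORF scan working directly on codon strings,
# independent of the package's run detection
ref_orf_peptides <- function(seq, min_aa) {
  gc <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
  peps <- character(0)
  for (s in c(seq, rc)) {
    for (f in 0:2) {
      ch <- substring(s, f + 1, nchar(s))
      ncod <- nchar(ch) %/% 3
      if (ncod < 1) next
      aa <- character(ncod)
      for (k in seq_len(ncod)) {
        cod <- substr(ch, 3 * k - 2, 3 * k)
        aa[k] <- if (grepl("N", cod)) "X" else gc[[cod]]
      }
      cur <- character(0)
      for (k in seq_len(ncod)) {
        if (aa[k] == "*") {
          if (length(cur) >= min_aa) peps <- c(peps, paste(cur, collapse = ""))
          cur <- character(0)
        } else cur <- c(cur, aa[k])
      }
      if (length(cur) >= min_aa) peps <- c(peps, paste(cur, collapse = ""))
    }
  }
  sort(peps)
}

# printed characterization values of the 18 mature armadillidins
# (organism id, residue length, average MW in Da, glycine %, theoretical pI)
table2_expected <- data.frame(
  id = c("A_assimile", "A_depressum", "A_maculatum", "A_nasatum",
         "A_tunisiense", "A_versicolor", "A_vulgare_H", "A_vulgare_Q",
         "A_officinalis", "C_elongata", "E_purpurascens", "P_dilatatus",
         "P_dispar", "P_laevis", "P_muscorum", "P_pruinosus", "P_scaber",
         "O_asellus"),
  length = c(55L, 59L, 53L, 56L, 53L, 53L, 53L, 53L, 129L, 48L, 49L, 47L,
             48L, 46L, 46L, 57L, 50L, 57L),
  mw = c(5354.8, 5726.1, 5252.6, 5485.9, 5268.7, 5263.6, 5259.6, 5250.6,
         13190.1, 5150.5, 4892.3, 4490.7, 4855.2, 4729.1, 4829.2, 5307.6,
         4709.0, 5485.9),
  gly = c(50.9, 49.2, 49.1, 50.0, 49.1, 49.1, 47.2, 47.2, 24.8, 45.8,
          46.9, 57.4, 52.1, 50.0, 45.7, 54.4, 58.0, 52.6),
  pi = c(11.4, 12.1, 11.9, 11.6, 11.0, 12.1, 12.0, 12.0, 8.6, 10.1, 11.4,
         10.1, 9.8, 9.8, 10.6, 11.6, 10.2, 11.7)
)

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
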