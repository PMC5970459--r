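# Independent oracles, implemented without reference to the package internals.

# Exhaustive affine-gap Smith-Waterman in plain R: full M / gap-in-subject /
# gap-in-query matrices, gap of length k costs go + k * ge, first maximal
# cell in row-major order, traceback preferring diagonal > up > left.
r_sw_align <- function(query, subject, match = 1, mismatch = -3,
                       go = 5, ge = 2) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  NEG <- -1e18
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  open <- go + ge
  best <- 0; bi <- 0; bj <- 0
  for (i in 1:n) for (j in 1:m) {
    sc <- if (q[i] == s[j]) match else mismatch
    d <- max(M[i, j], Ix[i, j], Iy[i, j])
    M[i + 1, j + 1] <- max(0, d + sc)
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - open, Ix[i, j + 1] - ge)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - open, Iy[i + 1, j] - ge)
    if (M[i + 1, j + 1] > best) {
      best <- M[i + 1, j + 1]; bi <- i; bj <- j
    }
  }
  if (best <= 0) {
    return(list(score = 0, q_start = 0L, q_end = 0L, s_start = 0L,
                s_end = 0L, q_aln = "", s_aln = ""))
  }
  qa <- character(0); sa <- character(0)
  i <- bi; j <- bj; state <- "M"
  repeat {
    if (state == "M") {
      sc <- if (q[i] == s[j]) match else mismatch
      qa <- c(q[i], qa); sa <- c(s[j], sa)
      v <- M[i + 1, j + 1] - sc
      i <- i - 1; j <- j - 1
      if (v <= 0) break
      state <- if (M[i + 1, j + 1] == v) "M"
        else if (Ix[i + 1, j + 1] == v) "Ix" else "Iy"
    } else if (state == "Ix") {
      qa <- c(q[i], qa); sa <- c("-", sa)
      v <- Ix[i + 1, j + 1]
      state <- if (M[i, j + 1] - open == v) "M" else "Ix"
      i <- i - 1
    } else {
      qa <- c("-", qa); sa <- c(s[j], sa)
      v <- Iy[i + 1, j + 1]
      state <- if (M[i + 1, j] - open == v) "M" else "Iy"
      j <- j - 1
    }
  }
  list(score = best, q_start = i, q_end = bi, s_start = j, s_end = bj,
       q_aln = paste(qa, collapse = ""), s_aln = paste(sa, collapse = ""))
}

# Brute-force AUC over all pairs, ties counted half.
brute_auc <- function(a, b) {
  tot <- 0
  for (x in b) for (y in a) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(a) * length(b))
}

# All-occurrence substring scan (naive), 0-based half-open starts.
brute_occurrences <- function(pattern, text) {
  L <- nchar(pattern)
  starts <- integer(0)
  for (p in seq_len(nchar(text) - L + 1L)) {
    if (substr(text, p, p + L - 1L) == pattern) starts <- c(starts, p - 1L)
  }
  starts
}

# Brute-force adapter cut: leftmost suffix/prefix overlap >= min_overlap.
brute_trim <- function(read, adapter, min_overlap = 8L) {
  L <- nchar(read); A <- nchar(adapter)
  for (p in seq_len(L)) {
    k <- min(L - p + 1L, A)
    if (k < min_overlap) break
    if (substr(read, p, p + k - 1L) == substr(adapter, 1L, k)) {
      return(substr(read, 1L, p - 1L))
    }
  }
  read
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# A tiny deterministic two-miRNA reference used across tests.
toy_reference <- function() {
  mat <- data.frame(
    mature_id = c("toy-miR-1-5p", "toy-miR-2-3p"),
    sequence = c("ACGTTGCAGGTCCAATGCAT", "TTAGGACCGGCAATCCTGAAC"),
    stringsAsFactors = FALSE)
  mat$length <- nchar(mat$sequence)
  prec <- data.frame(
    precursor_id = c("toy-mir-1", "toy-mir-2"),
    sequence = c(
      paste0("GGGAA", mat$sequence[1], "TGCCA",
             strrep("GATTC", 6)),
      paste0(strrep("CCAAG", 6), "AT", mat$sequence[2], "GCTTACC")),
    stringsAsFactors = FALSE)
  prec$length <- nchar(prec$sequence)
  list(matures = mat, precursors = prec,
       placements = map_mature_to_precursors(mat, prec))
}
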