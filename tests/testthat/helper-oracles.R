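# Independent brute-force oracles used across the suite. These are kept
# deliberately naive and separate from the package implementations.

# --- Smith-Waterman affine-gap DP oracle (gap of length L costs
#     open + L * ext, matching the package's convention) -----------------
sw_oracle <- function(a, b, mat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(-Inf, n + 1, m + 1)   # ends in aligned pair
  X <- matrix(-Inf, n + 1, m + 1)   # ends in gap in b
  Y <- matrix(-Inf, n + 1, m + 1)   # ends in gap in a
  best <- 0
  for (i in seq_len(n + 1)) M[i, 1] <- 0
  for (j in seq_len(m + 1)) M[1, j] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# --- per-base chain projection oracle --------------------------------
project_base_oracle <- function(pos, chain) {
  t_pos <- chain$t_start; q_pos <- chain$q_start
  b <- chain$blocks
  for (k in seq_len(nrow(b))) {
    if (pos >= t_pos && pos < t_pos + b$size[k]) {
      q <- q_pos + (pos - t_pos)
      if (chain$q_strand == "-") q <- chain$q_size - 1 - q
      return(q)
    }
    if (k < nrow(b)) {
      t_pos <- t_pos + b$size[k] + b$dt[k]
      q_pos <- q_pos + b$size[k] + b$dq[k]
    }
  }
  NA_real_
}

# forward-frame query positions covered by mapping iv through chain
projected_positions <- function(ivs) {
  unlist(lapply(ivs, function(iv) seq(iv$start, iv$end - 1)))
}

# --- all-windows peptide scanner -------------------------------------
peptide_oracle <- function(pep, target, background) {
  k <- nchar(pep)
  windows_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1),
           character(1))
  }
  in_target <- pep %in% windows_of(target)
  hd <- function(x, y) sum(utf8ToInt(x) != utf8ToInt(y))
  dists <- unlist(lapply(background, function(bg)
    vapply(windows_of(bg), hd, numeric(1), y = pep)), use.names = FALSE)
  mind <- if (length(dists)) min(dists) else Inf
  list(unique = in_target && mind >= 2, min_distance = mind)
}

# --- exhaustive parsimony on the rooted 4-taxon tree ((A,B),(C,D)) ----
# per-column minimum changes over all labelings of the 3 internal nodes
parsimony_oracle_4tax <- function(col_states, alphabet = c("A", "C")) {
  best <- Inf
  for (r in alphabet) for (ab in alphabet) for (cd in alphabet) {
    cost <- (r != ab) + (r != cd) +
      (ab != col_states[1]) + (ab != col_states[2]) +
      (cd != col_states[3]) + (cd != col_states[4])
    best <- min(best, cost)
  }
  best
}

# --- Benjamini-Hochberg step-up, written directly from the rule -------
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# --- adjusted Rand index ----------------------------------------------
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  d <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  exp_a <- b * d / choose(n, 2)
  max_a <- (b + d) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}

# random protein helper for alignment tests
rand_prot <- function(len, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                        "I", "K", "L", "M", "N", "P", "Q",
                                        "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
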