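# Independent oracles used to verify the package's implementations. These
# share no code with the package internals beyond standard tables.

# --- affine-gap global alignment score (Gotoh), Biostrings convention:
# a gap of length L costs open + L * extend
gotoh_score <- function(a, b, submat, open = 10, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- -open - extend * (i - 1)
  for (j in seq_len(m) + 1) Y[1, j] <- -open - extend * (j - 1)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend,
                     Y[i - 1, j] - open - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend,
                     X[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive Nei-Gojobori oracle: direct enumeration of site fractions
# and recursive enumeration of all mutational pathways
ng_oracle_sites <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  s <- 0
  for (cd in codons) {
    for (pos in 1:3) {
      for (bb in setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos))) {
        mut <- cd; substr(mut, pos, pos) <- bb
        if (gc[[mut]] != "*" && gc[[mut]] == gc[[cd]]) s <- s + 1 / 3
      }
    }
  }
  s
}

ng_oracle_paths <- function(from, to) {
  gc <- Biostrings::GENETIC_CODE
  recurse <- function(cur) {
    if (cur == to) return(list(c(0, 0)))
    out <- list()
    for (pos in which(strsplit(cur, "")[[1]] != strsplit(to, "")[[1]])) {
      nxt <- cur; substr(nxt, pos, pos) <- substr(to, pos, pos)
      if (gc[[nxt]] == "*" && nxt != to) next
      step <- if (gc[[nxt]] == gc[[cur]]) c(1, 0) else c(0, 1)
      for (tail_counts in recurse(nxt))
        out[[length(out) + 1L]] <- step + tail_counts
    }
    out
  }
  paths <- recurse(from)
  if (length(paths)) {
    Reduce(`+`, paths) / length(paths)
  } else {
    # all pathways blocked by stops: split raw differences by the mean
    # synonymous fraction at the differing positions
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    fr <- function(cd, p) {
      s <- 0
      for (bb in setdiff(c("A", "C", "G", "T"), substr(cd, p, p))) {
        mut <- cd; substr(mut, p, p) <- bb
        if (gc[[mut]] != "*" && gc[[mut]] == gc[[cd]]) s <- s + 1 / 3
      }
      s
    }
    gc <- Biostrings::GENETIC_CODE
    f <- mean(vapply(pos, function(p) (fr(from, p) + fr(to, p)) / 2,
                     numeric(1)))
    c(length(pos) * f, length(pos) * (1 - f))
  }
}

ng_oracle <- function(cds_a, cds_b) {
  S <- (ng_oracle_sites(cds_a) + ng_oracle_sites(cds_b)) / 2
  N <- nchar(cds_a) - S
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  d <- Reduce(`+`, Map(ng_oracle_paths, ca, cb))
  list(S = S, N = N, Sd = d[1], Nd = d[2])
}

# --- brute-force step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- Spearman correlation from average ranks, by the Pearson formula
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- random sense codons / codon pairs with bounded differences
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_codon_pair <- function(max_diff = 2) {
  sc <- sense_codons()
  repeat {
    a <- sample(sc, 1)
    b <- a
    k <- sample(0:max_diff, 1)
    if (k > 0) {
      for (pos in sample(1:3, k)) {
        substr(b, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                              substr(b, pos, pos)), 1)
      }
    }
    if (Biostrings::GENETIC_CODE[[b]] != "*") return(c(a, b))
  }
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}
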