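# Independent oracles and small fixture builders used across the suite.
# Each oracle is a deliberately naive implementation kept separate from the
# package code paths it checks.

# Build an msa from bare strings
make_msa <- function(..., reference_id = NULL) {
  seqs <- c(...)
  ids <- sprintf("s%d", seq_along(seqs))
  msa(ids, seqs, reference_id = reference_id)
}

# Oracle: probability that a fixed window of length w is free of S variant
# columns, by exhaustive enumeration of all C(L, S) placements.
enum_window_pvalue <- function(w, S, L) {
  if (S == 0) return(1)
  placements <- utils::combn(L, S, simplify = FALSE)
  window <- seq_len(w)  # any fixed window; uniformity makes the choice free
  mean(vapply(placements, function(p) !any(p %in% window), TRUE))
}

# Oracle: recover a rotation offset by brute-force scan of all rotations.
brute_rotation_offset <- function(sequence, anchor) {
  L <- nchar(sequence)
  for (k in 0:(L - 1)) {
    rot <- paste0(substr(sequence, k + 1, L), substr(sequence, 1, k))
    if (startsWith(rot, anchor)) return(k)
  }
  NA_integer_
}

# Oracle: TN93 distance evaluated directly from its closed form, written
# independently of the package's vectorized pair code.
tn93_closed_form <- function(a, b) {
  n <- length(a)
  P1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A")) / n
  P2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C")) / n
  Q <- sum(a != b) / n - P1 - P2
  freq <- function(x) (sum(a == x) + sum(b == x)) / (2 * n)
  gA <- freq("A"); gC <- freq("C"); gG <- freq("G"); gT <- freq("T")
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  -k1 * log(1 - P1 / k1 - Q / (2 * gR)) -
    k2 * log(1 - P2 / k2 - Q / (2 * gY)) -
    k3 * log(1 - Q / (2 * gR * gY))
}

# Oracle: UPGMA cophenetic distances via hclust's independent average-
# linkage implementation.
hclust_cophenetic <- function(d) {
  as.matrix(stats::cophenetic(stats::hclust(stats::as.dist(d), "average")))
}

# Random symmetric distance matrix without ties (continuous entries).
random_dist_matrix <- function(n, labels = paste0("t", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  d + t(d)
}

# Random small alignment matrix panel for property tests.
random_panel <- function(n_seqs, n_cols, p_variant = 0.3) {
  base <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  mat <- matrix(rep(base, each = n_seqs), nrow = n_seqs)
  for (j in which(stats::runif(n_cols) < p_variant)) {
    alt <- sample(setdiff(c("A", "C", "G", "T", "-"), base[j]), 1)
    k <- sample.int(floor(n_seqs / 2), 1)
    mat[sample.int(n_seqs, k), j] <- alt
  }
  msa(sprintf("s%d", seq_len(n_seqs)), apply(mat, 1, paste, collapse = ""),
      reference_id = "s1")
}

# Write a pileup line set to a temp file and return the path.
write_pileup_lines <- function(lines) {
  path <- tempfile(fileext = ".pileup")
  writeLines(lines, path)
  path
}
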