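# Independent brute-force oracles and small fixture builders.

# Dense named sparse matrix from a plain matrix.
as_counts <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  Matrix::Matrix(m, sparse = TRUE)
}

# Exhaustive two-sided rank-sum permutation p-value, from raw values:
# enumerate every assignment of the pooled observations to group A.
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); na <- length(x)
  r <- rank(pooled)
  e0 <- na * (n + 1) / 2
  obs <- sum(r[seq_len(na)])
  sets <- utils::combn(n, na)
  tsum <- colSums(matrix(r[sets], nrow = na))
  mean(abs(tsum - e0) >= abs(obs - e0) - 1e-9)
}

# All permutations of a vector (including duplicates once each).
all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (u in unique(v)) {
    i <- match(u, v)
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(u, rest)
  }
  out
}

# Kendall S by direct double loop.
oracle_mk_s <- function(x) {
  s <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  s
}

# Exact permutation distribution of S over distinct orderings; returns the
# S values (one per distinct permutation).
oracle_mk_s_values <- function(x) {
  vapply(all_permutations(sort(x)), oracle_mk_s, numeric(1))
}

# Weighted-KS walk score computed directly from one expression vector.
oracle_walk_score <- function(x, genes, set, tau = 1) {
  N <- length(x)
  midrank <- rank(-x, ties.method = "average")
  ord <- order(-x, genes)
  inset <- genes %in% set
  w <- (N - midrank + 1)^tau
  steps <- ifelse(inset[ord],
                  w[ord] / sum(w[inset]),
                  -1 / (N - sum(inset)))
  walk <- cumsum(steps)
  max(c(walk, 0)) + min(c(walk, 0))
}

# Adjusted Rand index between two label vectors.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
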