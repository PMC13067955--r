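# Independent oracles, deliberately naive: these re-derive expected values
# by enumeration or plain loops and never share code with the package.

# minimum path-sum over ALL monotone warping paths, by explicit enumeration
dtw_enum <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- min(best, acc); return(invisible()) }
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    if (i < n) rec(i + 1, j, acc)
    if (j < m) rec(i, j + 1, acc)
  }
  rec(1, 1, 0)
  best
}

# plain-loop mean silhouette with the singleton-contributes-0 convention
silhouette_brute <- function(D, labels) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0) { s[i] <- 0; next }
    a <- mean(D[i, mates])
    b <- Inf
    for (k in setdiff(unique(labels), own))
      b <- min(b, mean(D[i, labels == k]))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# hypergeometric pmf by enumerating every size-n subset of 1..N,
# category = elements 1..K
hyper_enum_pmf <- function(N, K, n) {
  if (n == 0) return(stats::setNames(1, "0"))
  subs <- utils::combn(N, n)
  counts <- colSums(subs <= K)
  table(factor(counts, levels = 0:n)) / ncol(subs)
}

make_curve <- function(od, strain = "s", rep = 1L, dt = 0.25) {
  growth_curve(strain, rep, seq(0, by = dt, length.out = length(od)), od)
}

# noiseless sigmoid for fixtures
sigmoid_od <- function(n = 96, A = 0.8, mu = 0.7, lambda = 2, base = 0.06,
                       dt = 0.25) {
  t <- seq(0, by = dt, length.out = n)
  base + A * exp(-exp(mu * exp(1) / A * (lambda - t) + 1))
}
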