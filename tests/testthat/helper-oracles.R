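# Independent oracles used to check the package's statistics. They share no
# code path with the implementation: log-factorials are accumulated by hand
# and tails enumerated term by term.

# Upper-tail P(X >= o) for the overlap of a random `list_size` draw with a
# fixed set of `set_size` in a universe of `U`, by direct enumeration.
hyper_tail_oracle <- function(o, list_size, set_size, U) {
  lf <- c(0, cumsum(log(seq_len(max(U, 1)))))  # lf[n+1] = log(n!)
  lchoose_ <- function(n, k) lf[n + 1] - lf[k + 1] - lf[n - k + 1]
  k_min <- max(0, list_size + set_size - U)
  k_max <- min(list_size, set_size)
  if (o > k_max) return(0)
  ks <- max(o, k_min):k_max
  sum(exp(lchoose_(set_size, ks) + lchoose_(U - set_size, list_size - ks) -
            lchoose_(U, list_size)))
}

# Full tail vector P(X >= o) for every o in 0..min(list,set), same route.
hyper_tail_oracle_all <- function(list_size, set_size, U) {
  vapply(0:min(list_size, set_size), hyper_tail_oracle,
         numeric(1), list_size = list_size, set_size = set_size, U = U)
}

# Benjamini-Hochberg step-up written directly from its definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Topological overlap by the defining triple loop.
tom_oracle <- function(adj) {
  a <- adj; diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(adj)
  tom
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Area under the ROC curve of score-ranking (lower score = more positive).
auroc <- function(p, is_positive) {
  ok <- !is.na(p)
  r <- rank(-p[ok])          # higher rank = smaller p
  pos <- is_positive[ok]
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
}
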