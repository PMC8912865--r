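# Independent brute-force oracles used to validate the matrix/BFS
# implementations. These are deliberately naive and share no code with the
# package internals.

# TOM by explicit triple loop over the formula
brute_tom <- function(a) {
  n <- nrow(a)
  tom <- diag(1, n)
  dimnames(tom) <- dimnames(a)
  k <- numeric(n)
  for (i in seq_len(n)) k[i] <- sum(a[i, -i])
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) L <- L + a[i, u] * a[u, j]
      }
      tom[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# all simple paths between two nodes by depth-first enumeration;
# returns list(distance, n_geodesics) from the minimal-length paths
brute_geodesics <- function(adj, source, target) {
  if (source == target) return(list(distance = 0L, n_geodesics = 1))
  paths <- list()
  dfs <- function(node, visited) {
    for (nb in adj[[node]]) {
      if (nb == target) {
        paths[[length(paths) + 1L]] <<- c(visited, nb)
      } else if (!nb %in% visited) {
        dfs(nb, c(visited, nb))
      }
    }
  }
  dfs(source, source)
  if (!length(paths)) return(list(distance = NA_integer_, n_geodesics = 0))
  lens <- vapply(paths, length, integer(1)) - 1L
  list(distance = min(lens), n_geodesics = sum(lens == min(lens)))
}

# hypergeometric upper tail P(X >= k) by explicit binomial-coefficient sum
brute_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# scale-free fit by a fresh two-pass binned regression (no lm)
brute_scale_free_fit <- function(a, n_bins = 10) {
  k <- rowSums(a) - diag(a)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  dk <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(dk) & dk > 0
  x <- log10(dk[keep]); y <- log10(pk[keep])
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  r2 <- (sum((x - mx) * (y - my)))^2 / (sum((x - mx)^2) * sum((y - my)^2))
  list(signed_r2 = r2 * (-sign(slope)), slope = slope)
}
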