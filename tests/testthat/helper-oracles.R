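# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# brute-force Ward agglomerator: at each step recompute, for every pair of
# current clusters, the increase in total within-cluster sum of squared
# deviations from the cluster means, and merge the pair with the smallest
# increase (ties: lowest pair of slot indices). Returns hclust-style merge
# rows (sorted within row) for comparison with ward_cluster().
bruteforce_ward_merges <- function(m) {
  n <- nrow(m)
  wss <- function(idx) {
    x <- m[idx, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merges <- matrix(0L, n - 1L, 2L)
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_inc <- Inf
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (j <= i) next
        inc <- wss(c(members[[i]], members[[j]])) -
          wss(members[[i]]) - wss(members[[j]])
        if (inc < best_inc - 1e-12) { best_inc <- inc; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merges[step, ] <- sort(c(ids[i], ids[j]))
    members[[i]] <- c(members[[i]], members[[j]])
    ids[i] <- step
    members[[j]] <- NULL
    ids <- ids[-j]
  }
  merges
}

# quadrature oracle for the two-sided correlation p-value: numerically
# integrate the t density tail rather than calling a distribution function
quadrature_cor_pvalue <- function(r, n) {
  df <- n - 2
  t <- abs(r) * sqrt(df) / sqrt(1 - r^2)
  2 * stats::integrate(function(x) stats::dt(x, df), t, Inf,
                       rel.tol = 1e-12)$value
}

# deterministic random draws for fixtures
with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

# strip provenance comment lines so byte comparisons ignore the config hash
read_table_body <- function(path) {
  lines <- readLines(path)
  lines[!startsWith(lines, "#")]
}
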