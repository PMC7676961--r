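# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from its definition, not through the package's
# own code paths.

# tie-corrected Kruskal-Wallis H from the rank-sum formula
oracle_kw <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / tabulate(as.integer(factor(groups)))) -
    3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Benjamini-Hochberg step-up computed literally: sort, scale by m/i,
# enforce monotonicity from the largest, cap, restore order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# monotone classification via sortedness, an independent route
oracle_direction <- function(means) {
  if (!is.unsorted(means) && !all(means == means[1])) return("MI")
  if (!is.unsorted(rev(means)) && !all(means == means[1])) return("MD")
  "none"
}

# exhaustive threshold enumeration for one cumulative split
oracle_split_error <- function(values, lower,
                               direction = "increasing") {
  if (direction == "decreasing") {
    res <- oracle_split_error(-values, lower, "increasing")
    res$line <- -res$line
    return(res)
  }
  cands <- c(-Inf, sort(unique(values)))
  mis <- vapply(cands, function(t) {
    sum(lower & values > t) + sum(!lower & values <= t)
  }, 0)
  j <- which.min(mis)
  list(misclassified = as.integer(mis[j]), line = cands[j])
}

oracle_detotal <- function(values, stages, direction = "increasing") {
  lev <- sort(unique(stages))
  sum(vapply(seq_len(length(lev) - 1), function(k) {
    oracle_split_error(values, stages %in% lev[seq_len(k)],
                       direction)$misclassified
  }, 0L))
}

# small fixtures -------------------------------------------------------------

path_net <- function() {
  gene_network(c("A", "B", "C"),
               rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
}

edgeless_net <- function(genes = c("A", "B", "C")) {
  p <- length(genes)
  gene_network(genes, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                           dims = c(p, p)))
}

random_net <- function(p, prob = 0.05, seed = 1) {
  simulate_network(p, "erdos_renyi", prob, seed = seed)
}

write_edge_lines <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
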