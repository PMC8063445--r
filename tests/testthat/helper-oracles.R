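# Independent brute-force oracles. These re-derive expected results from first
# principles and must stay independent of the package code paths they check.

# Benjamini-Hochberg step-up, straight from the definition:
# adj_(i) = min_{j >= i} min(1, m * p_(j) / j) on ascending order statistics.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# Greedy Ward agglomeration recomputing the criterion from scratch at every
# step: merge the pair of clusters with the smallest increase in
# within-cluster sum of squares, Delta = |A||B|/(|A|+|B|) * ||mean_A-mean_B||^2.
# Ties: lexicographically smallest (min index, max index) pair.
brute_ward_partition <- function(x, k) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  while (length(clusters) > k) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- x[clusters[[i]], , drop = FALSE]
        b <- x[clusters[[j]], , drop = FALSE]
        d <- (nrow(a) * nrow(b)) / (nrow(a) + nrow(b)) *
          sum((colMeans(a) - colMeans(b))^2)
        key <- c(min(clusters[[i]][1], clusters[[j]][1]),
                 max(clusters[[i]][1], clusters[[j]][1]))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, key = key)
          best_d <- d
        }
      }
    }
    clusters[[best$i]] <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$j]] <- NULL
  }
  labels <- integer(nrow(x))
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  labels
}

# Two label vectors describe the same partition (up to relabeling)?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# Exclusive overlap counts by per-gene membership enumeration.
brute_overlap <- function(member_sets) {
  universe <- unique(unlist(member_sets))
  patterns <- vapply(universe, function(g) {
    paste(vapply(member_sets, function(m) g %in% m, logical(1)), collapse = "|")
  }, character(1))
  table(patterns)
}
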