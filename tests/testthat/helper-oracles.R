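# Independent oracle implementations used across the suite. These are kept
# deliberately naive (enumeration, textbook formulas) and must not share code
# with the package internals they check.

# Upper-tail hypergeometric probability P(X >= k) by direct summation over
# the tail, using log-binomials for numerical stability.
oracle_hyper_tail <- function(k, set_size, universe, query) {
  i <- seq.int(k, min(set_size, query))
  sum(exp(lchoose(set_size, i) + lchoose(universe - set_size, query - i) -
            lchoose(universe, query)))
}

# Tie-corrected two-group Kruskal-Wallis statistic from the textbook rank
# formula.
oracle_kw <- function(values, in_group) {
  N <- length(values)
  rk <- rank(values)
  groups <- split(rk, in_group)
  H <- 12 / (N * (N + 1)) *
    sum(vapply(groups, function(g) length(g) * (mean(g) - (N + 1) / 2)^2, 1))
  tie_sizes <- table(values)
  H / (1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N))
}

# Agglomerative Ward clustering by explicit Lance-Williams recursion on
# squared distances (the ward.D2 convention: heights are unsquared).
# Returns the merge heights and the sets merged at each step.
oracle_ward <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(NA, NA); best_val <- Inf
    for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
      if (d2[i, j] < best_val) { best_val <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    heights[step] <- sqrt(best_val)
    merges[[step]] <- sort(c(active[[i]], active[[j]]))
    ni <- sizes[i]; nj <- sizes[j]
    new_row <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      new_row[k] <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                       nk * d2[i, j]) / (ni + nj + nk)
    }
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], new_row[keep]),
                c(new_row[keep], 0))
    active <- c(active[keep], list(sort(c(merges[[step]]))))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(heights = heights, merges = merges)
}

# Sets merged at each hclust step, as sorted leaf-index vectors.
hclust_merge_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    members <- integer()
    for (x in tree$merge[s, ]) {
      members <- c(members, if (x < 0) -x else sets[[x]])
    }
    sets[[s]] <- sort(members)
  }
  sets
}

# A small fully-specified dataset for plumbing tests.
tiny_dataset <- function(seed = 42L) {
  generate_dataset(sim_config(n_genes = 120L, n_cells = 40L, n_patients = 12L,
                              n_pathways = 10L,
                              pathway_size_range = c(5L, 15L),
                              signature_size = 10L, n_planted = 2L,
                              planted_overlap = 5L, seed = seed))
}
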