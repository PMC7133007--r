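# Independent oracles used by the tests.  These deliberately take different
# computational routes from the package implementations they check.

# ---- exhaustive unrooted topology enumeration + least-squares fit ----------

# All unrooted binary topologies over n >= 3 labelled tips, built by
# inserting each new tip on every edge of every smaller topology.
# Returns a list of 2-column edge matrices; tips are 1..n.
enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  base <- matrix(c(n + 1, 1, n + 1, 2, n + 1, 3), ncol = 2, byrow = TRUE)
  trees <- list(base)
  if (n == 3) return(trees)
  for (tip in 4:n) {
    nxt <- list()
    for (tr in trees) {
      new_internal <- max(tr) + 1L
      for (e in seq_len(nrow(tr))) {
        t2 <- rbind(
          tr[-e, , drop = FALSE],
          c(tr[e, 1], new_internal),
          c(new_internal, tr[e, 2]),
          c(new_internal, tip)
        )
        nxt[[length(nxt) + 1L]] <- t2
      }
    }
    trees <- nxt
  }
  trees
}

# Ordinary least-squares branch lengths for a topology given a distance
# matrix over tips 1..n; returns the residual sum of squares and fitted
# pairwise distances.
ls_fit_topology <- function(edges, d) {
  n <- nrow(d)
  g <- igraph::graph_from_edgelist(apply(edges, 2, as.character),
                                   directed = FALSE)
  pair <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pair), nrow(edges))
  for (r in seq_len(nrow(pair))) {
    p <- igraph::shortest_paths(g, as.character(pair[r, 1]),
                                as.character(pair[r, 2]),
                                output = "epath")$epath[[1]]
    A[r, as.integer(p)] <- 1
  }
  y <- d[pair]
  fit <- qr.solve(crossprod(A), crossprod(A, y))
  list(rss = sum((A %*% fit - y)^2), lengths = as.vector(fit))
}

# Best-fitting topology by exhaustive search; returns its edge matrix.
best_topology_exhaustive <- function(d) {
  trees <- enumerate_topologies(nrow(d))
  rss <- vapply(trees, function(tr) ls_fit_topology(tr, d)$rss, numeric(1))
  trees[[which.min(rss)]]
}

# Unrooted bipartition set of an edge-matrix topology (tips 1..n), as a
# canonical character set, for topology comparison.
topo_splits <- function(edges, n) {
  g <- igraph::graph_from_edgelist(apply(edges, 2, as.character),
                                   directed = FALSE)
  internal <- edges[edges[, 1] > n & edges[, 2] > n, , drop = FALSE]
  splits <- character(0)
  for (e in seq_len(nrow(internal))) {
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, as.character(internal[e, ]))
    )
    comp <- igraph::components(g2)$membership
    side <- sort(as.integer(names(comp)[comp == comp[[as.character(internal[e, 1])]]]))
    side <- side[side <= n]
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    splits <- c(splits, paste(sort(side), collapse = ","))
  }
  sort(splits)
}

# Bipartition set of an ape::phylo with tip labels t1..tn mapping to 1..n.
phylo_splits <- function(tree, labels) {
  n <- length(labels)
  unrooted <- ape::unroot(tree)
  parts <- ape::prop.part(unrooted)
  splits <- character(0)
  for (p in parts) {
    side <- sort(match(attr(parts, "labels")[p], labels))
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    splits <- c(splits, paste(side, collapse = ","))
  }
  sort(unique(splits))
}

# ---- exact rank-sum null by bitmask enumeration ----------------------------

# Two-sided permutation p-value for the rank-sum of the first n_a of the
# pooled values, enumerating subsets via bit masks (total n <= ~20).
rank_sum_bruteforce <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals); n_a <- length(a)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != n_a) next
    total <- total + 1L
    w <- sum(r[bits == 1L])
    if (abs(w - mu) >= abs(w_obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# ---- small simulated populations -------------------------------------------

small_population <- function(n_lineages = 3, core_size = 10,
                             divergence_between = 0.03, gain_rate = 5,
                             seed = 42, genomes = FALSE, ...) {
  simulate_lineages(
    sim_config(n_lineages = n_lineages, core_size = core_size,
               accessory_pool_size = 50, gain_rate = gain_rate,
               gene_length_range = c(300L, 600L),
               divergence_between = divergence_between,
               genome_length = 60000L, seed = seed, ...),
    genomes = genomes
  )
}

random_gene_table <- function(n_genes, len = 600L, strain = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    gene_id = sprintf("%s_g%03d", strain, seq_len(n_genes)),
    strain_id = strain,
    sequence = vapply(rep(len, n_genes), function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
  )
}
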