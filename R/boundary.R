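# Genetic-boundary statistic: among the gene families shared one-to-one by a
# pair of strains, the fraction whose two sequences are byte-identical.
# Deeply diverged lineages show ratios near zero; clonal relatives near one.

# Per-family, per-strain unique-member sequence codes: integer matrix
# (families x strains), NA where the strain has zero or multiple members.
one_to_one_codes <- function(genes, families) {
  check_gene_table(genes)
  fam <- families |>
    inner_join(genes, by = c("gene_id", "strain_id"))
  if (nrow(fam) != nrow(families)) {
    abort("families reference genes absent from the gene table")
  }
  strains <- unique(families$strain_id)
  fam_ids <- unique(families$family_id)
  counts <- table(factor(fam$family_id, fam_ids),
                  factor(fam$strain_id, strains))
  seq_code <- match(fam$sequence, unique(fam$sequence))
  H <- matrix(NA_integer_, length(fam_ids), length(strains),
              dimnames = list(fam_ids, strains))
  single <- fam |>
    mutate(code = seq_code) |>
    group_by(.data$family_id, .data$strain_id) |>
    filter(dplyr::n() == 1L) |>
    ungroup()
  H[cbind(match(single$family_id, fam_ids),
          match(single$strain_id, strains))] <- single$code
  H
}

#' Identical-sequence ratio between two strains
#'
#' Counts the families with exactly one member in each of the two strains
#' (`shared`), how many of those pairs are exactly equal nucleotide strings
#' (`identical` — no alignment, zero sequence degeneracy), and their ratio.
#'
#' @param genes Gene tibble covering both strains.
#' @param families Family tibble built over a collection containing both.
#' @param strain_a,strain_b Strain ids.
#' @return A one-row tibble: `strain_a`, `strain_b`, `shared`, `identical`,
#'   `ratio` (`NA` when no family is shared).
#' @export
identical_ratio <- function(genes, families, strain_a, strain_b) {
  H <- one_to_one_codes(genes, families)
  if (!all(c(strain_a, strain_b) %in% colnames(H))) {
    abort("both strains must appear in the family table")
  }
  if (strain_a == strain_b) {
    shared <- sum(!is.na(H[, strain_a]))
    ident <- shared
  } else {
    ok <- !is.na(H[, strain_a]) & !is.na(H[, strain_b])
    shared <- sum(ok)
    ident <- sum(H[ok, strain_a] == H[ok, strain_b])
  }
  tibble(strain_a = strain_a, strain_b = strain_b,
         shared = shared, identical = ident,
         ratio = if (shared > 0L) ident / shared else NA_real_)
}

#' Pairwise identical-ratio matrix over a strain collection
#'
#' @param genes Gene tibble.
#' @param families Family tibble from [build_families()].
#' @param strains Strain ids to include (default: all in `families`);
#'   duplicates are rejected.
#' @return An `identical_ratio_matrix` with symmetric `shared`, `identical`
#'   and `ratio` matrices (diagonal ratio 1); see [tidy()] and [autoplot()].
#' @export
ratio_matrix <- function(genes, families, strains = unique(families$strain_id)) {
  if (anyDuplicated(strains)) {
    abort(sprintf("duplicate strain id '%s' in strain list",
                  strains[duplicated(strains)][1]))
  }
  if (length(strains) < 2L) abort("ratio_matrix requires >= 2 strains")
  H <- one_to_one_codes(genes, families)[, strains, drop = FALSE]
  S <- length(strains)
  shared <- ident <- matrix(0L, S, S, dimnames = list(strains, strains))
  for (a in seq_len(S - 1L)) {
    for (b in (a + 1L):S) {
      ok <- !is.na(H[, a]) & !is.na(H[, b])
      shared[a, b] <- shared[b, a] <- sum(ok)
      ident[a, b] <- ident[b, a] <- sum(H[ok, a] == H[ok, b])
    }
  }
  diag(shared) <- colSums(!is.na(H))
  diag(ident) <- diag(shared)
  ratio <- ifelse(shared > 0L, ident / shared, NA_real_)
  diag(ratio) <- 1
  structure(list(strains = strains, shared = shared, identical = ident,
                 ratio = ratio),
            class = "identical_ratio_matrix")
}

#' @export
print.identical_ratio_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<identical_ratio_matrix> %d strains\n", length(x$strains)))
  print(round(x$ratio, digits))
  invisible(x)
}

#' @export
tidy.identical_ratio_matrix <- function(x, ...) {
  expand_idx <- which(upper.tri(x$ratio, diag = FALSE), arr.ind = TRUE)
  tibble(
    strain_a = x$strains[expand_idx[, 1L]],
    strain_b = x$strains[expand_idx[, 2L]],
    shared = x$shared[expand_idx],
    identical = x$identical[expand_idx],
    ratio = x$ratio[expand_idx]
  )
}

#' @rdname ratio_matrix
#' @param object,x An `identical_ratio_matrix`.
#' @param ... Unused.
#' @export
autoplot.identical_ratio_matrix <- function(object, ...) {
  d <- as_tibble(as.data.frame.table(object$ratio, responseName = "ratio")) |>
    rename(strain_a = "Var1", strain_b = "Var2")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$strain_a, y = .data$strain_b,
                                  fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "identical /\nshared") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write an identical-ratio matrix as a percentage TSV
#'
#' Percentages with one decimal, mirroring how such tables are reported.
#'
#' @param x An `identical_ratio_matrix`.
#' @param path Output file.
#' @export
write_ratio_matrix <- function(x, path) {
  pct <- round(100 * x$ratio, 1)
  df <- data.frame(strain = rownames(pct), pct, check.names = FALSE)
  readr_write_tsv(df, path)
}

#' Delineate clusters separated by genetic boundaries
#'
#' Strains are clustered as connected components of the graph whose edges
#' join pairs with identical-ratio at or above `threshold`; pairs with low
#' (or missing) ratios fall on different sides of a genetic boundary.
#'
#' @param x An `identical_ratio_matrix`.
#' @param threshold Ratio threshold in \[0, 1\]; default 0.10, below which
#'   diverged lineages typically fall.
#' @return A `boundary_clustering`: tibble (`strain_id`, `cluster`) plus
#'   `n_clusters` and the threshold.
#' @export
delineate_clusters <- function(x, threshold = 0.10) {
  stopifnot(inherits(x, "identical_ratio_matrix"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    abort("threshold must lie in [0, 1]")
  }
  r <- x$ratio
  r[is.na(r)] <- -Inf   # missing ratios break edges
  adj <- (r >= threshold) * 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # label clusters in order of first appearance
  lab <- match(comp, unique(comp))
  structure(list(
    clusters = tibble(strain_id = x$strains,
                      cluster = sprintf("B%d", lab)),
    n_clusters = length(unique(lab)),
    threshold = threshold
  ), class = "boundary_clustering")
}

#' @export
print.boundary_clustering <- function(x, ...) {
  cat(sprintf("<boundary_clustering> %d cluster(s) at threshold %.2f\n",
              x$n_clusters, x$threshold))
  print(x$clusters, n = 10)
  invisible(x)
}

#' @export
tidy.boundary_clustering <- function(x, ...) x$clusters

#' @export
glance.boundary_clustering <- function(x, ...) {
  tibble(n_clusters = x$n_clusters, threshold = x$threshold)
}
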