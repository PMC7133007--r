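# Pairwise homology under the 70/70 identity/coverage criterion, ortholog
# families as connected components, and core/pan-genome accumulation.

align_scoring <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = TRUE)
}

# Batch ends-free global alignment of paired sequence vectors.  Returns a
# tibble with identity (matches / aligned columns, gap columns counting as
# non-match), per-gene coverages (aligned columns / gene length), aligned
# column count and the homology call.
align_many <- function(seq_a, seq_b, ids_a, ids_b,
                       min_identity = 0.70, min_coverage = 0.70) {
  check_dna(seq_a, ids_a)
  check_dna(seq_b, ids_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seq_a), Biostrings::DNAStringSet(seq_b),
    type = "overlap", substitutionMatrix = align_scoring(),
    gapOpening = 5, gapExtension = 1
  )
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  cols <- nchar(pa)
  matches <- Biostrings::nmatch(aln)
  identity <- ifelse(cols > 0L, matches / cols, 0)
  coverage_a <- cols / nchar(seq_a)
  coverage_b <- cols / nchar(seq_b)
  tibble(
    gene_a = ids_a, gene_b = ids_b,
    identity = identity,
    coverage_a = coverage_a, coverage_b = coverage_b,
    aligned_length = as.integer(cols),
    is_homolog = identity > min_identity &
      pmin(coverage_a, coverage_b) > min_coverage
  )
}

#' Align two genes and call homology under the identity/coverage criterion
#'
#' Global alignment with free end gaps (match +1, mismatch -1, gap open 5,
#' gap extend 1).  Identity is matches over aligned columns with gap columns
#' counting as mismatches; coverage of each gene is the aligned column count
#' over that gene's length.  A pair is called homologous when identity is
#' strictly greater than `min_identity` and the smaller of the two coverages
#' is strictly greater than `min_coverage` — so a hit at exactly 70.000%
#' fails the default criterion.
#'
#' @param a,b One-row tibbles (or named lists) with `gene_id` and `sequence`.
#' @param min_identity,min_coverage Strict lower bounds, default 0.70.
#' @return A one-row tibble: `gene_a`, `gene_b`, `identity`, `coverage_a`,
#'   `coverage_b`, `aligned_length`, `is_homolog`.
#' @export
#' @examples
#' align_pair(list(gene_id = "x", sequence = "ACGTACGTAC"),
#'            list(gene_id = "y", sequence = "ACGTACGTTT"))
align_pair <- function(a, b, min_identity = 0.70, min_coverage = 0.70) {
  if (!nzchar(a$sequence) || !nzchar(b$sequence)) {
    abort("align_pair requires non-empty sequences")
  }
  align_many(a$sequence, b$sequence, a$gene_id, b$gene_id,
             min_identity, min_coverage)
}

# Candidate gene pairs sharing at least one k-mer.  Returns a two-column
# integer matrix of row indices into `genes` (i < j).
kmer_candidates <- function(sequences, k = 18L) {
  n <- length(sequences)
  idx <- rep.int(seq_len(n), pmax(nchar(sequences) - k + 1L, 0L))
  kmers <- unlist(lapply(sequences, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  by_kmer <- split(idx, kmers)
  pairs <- lapply(by_kmer, function(v) {
    v <- unique(v)
    if (length(v) < 2L) return(NULL)
    t(combn(sort(v), 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2L))
  unique(pairs)
}

#' All-vs-all homology search over a gene table
#'
#' Evaluates the pairwise criterion of [align_pair()] across every pair of
#' genes in the collection, including pairs within the same strain (paralog
#' detection).  By default a k-mer prefilter restricts full alignment to
#' pairs sharing at least one exact `k`-mer; at the default `k = 18` a pair
#' with identity above 0.70 over genes of a few hundred bp is expected to
#' share many exact 18-mers, while unrelated random genes essentially never
#' do.  With `prefilter = FALSE` every pair is aligned (the oracle mode).
#'
#' @param genes Gene tibble (`gene_id`, `strain_id`, `sequence`).
#' @param prefilter Logical; use the k-mer candidate filter.
#' @param k Prefilter k-mer size.
#' @param min_identity,min_coverage Passed to the homology criterion.
#' @return A hit tibble (one row per evaluated pair, columns as in
#'   [align_pair()] plus `strain_a`, `strain_b`).
#' @export
all_vs_all <- function(genes, prefilter = TRUE, k = 18L,
                       min_identity = 0.70, min_coverage = 0.70) {
  check_gene_table(genes)
  if (!nrow(genes)) abort("empty gene table")
  n <- nrow(genes)
  if (prefilter) {
    cand <- kmer_candidates(genes$sequence, k)
  } else {
    cand <- t(combn(seq_len(n), 2L))
    if (n < 2L) cand <- matrix(integer(0), ncol = 2L)
  }
  if (!nrow(cand)) {
    return(tibble(gene_a = character(0), gene_b = character(0),
                  strain_a = character(0), strain_b = character(0),
                  identity = numeric(0), coverage_a = numeric(0),
                  coverage_b = numeric(0), aligned_length = integer(0),
                  is_homolog = logical(0)))
  }
  i <- cand[, 1L]; j <- cand[, 2L]
  # Byte-identical sequences need no alignment.
  same <- genes$sequence[i] == genes$sequence[j]
  out <- vector("list", 2L)
  if (any(same)) {
    len <- nchar(genes$sequence[i[same]])
    out[[1L]] <- tibble(
      gene_a = genes$gene_id[i[same]], gene_b = genes$gene_id[j[same]],
      identity = 1, coverage_a = 1, coverage_b = 1,
      aligned_length = as.integer(len),
      is_homolog = TRUE
    )
  }
  if (any(!same)) {
    out[[2L]] <- align_many(
      genes$sequence[i[!same]], genes$sequence[j[!same]],
      genes$gene_id[i[!same]], genes$gene_id[j[!same]],
      min_identity, min_coverage
    )
  }
  strain_of <- setNames(genes$strain_id, genes$gene_id)
  bind_rows(out) |>
    mutate(strain_a = unname(strain_of[.data$gene_a]),
           strain_b = unname(strain_of[.data$gene_b])) |>
    select("gene_a", "gene_b", "strain_a", "strain_b", dplyr::everything()) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Build ortholog families by single linkage over the homolog graph
#'
#' Families are the connected components of the graph whose edges are
#' homologous pairs; genes with no homologs become singleton families.
#' Family identifiers are stable: each family is named after its
#' lexicographically smallest member.
#'
#' @param hits Hit tibble from [all_vs_all()] (or any tibble with `gene_a`,
#'   `gene_b`, `is_homolog`).
#' @param genes Gene tibble defining the full gene universe.
#' @return A family tibble (`family_id`, `gene_id`, `strain_id`); families
#'   partition the gene universe.
#' @export
build_families <- function(hits, genes) {
  check_gene_table(genes)
  edges <- hits |> filter(.data$is_homolog)
  unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), genes$gene_id)
  if (length(unknown)) {
    abort(sprintf("hit references unknown gene '%s'", unknown[1]))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = genes$gene_id)
  )
  comp <- igraph::components(g)$membership
  members <- split(names(comp), comp)
  fam_ids <- vapply(members, function(m) min(m), character(1))
  fam_of <- setNames(rep(fam_ids, lengths(members)), unlist(members))
  genes |>
    mutate(family_id = unname(fam_of[.data$gene_id])) |>
    select("family_id", "gene_id", "strain_id") |>
    arrange(.data$family_id, .data$gene_id)
}

#' Summarize ortholog families
#'
#' @param families Family tibble from [build_families()].
#' @return One row per family: member count, strain count, single-copy flag.
#' @export
family_summary <- function(families) {
  families |>
    group_by(.data$family_id) |>
    summarise(
      n_genes = dplyr::n(),
      n_strains = dplyr::n_distinct(.data$strain_id),
      is_single_copy = dplyr::n() == dplyr::n_distinct(.data$strain_id),
      .groups = "drop"
    )
}

#' Core genome: families present in every strain
#'
#' @param families Family tibble.
#' @param strains Character vector of strain ids defining "all strains"
#'   (default: every strain appearing in `families`).
#' @return The subset of `families` whose family is present in all strains.
#' @export
core_genome <- function(families, strains = unique(families$strain_id)) {
  if (!length(strains)) abort("empty strain list")
  pres <- families |>
    filter(.data$strain_id %in% strains) |>
    group_by(.data$family_id) |>
    summarise(n_strains = dplyr::n_distinct(.data$strain_id), .groups = "drop")
  core_ids <- pres$family_id[pres$n_strains == length(strains)]
  families |> filter(.data$family_id %in% core_ids)
}

curve_for_order <- function(pres, order_idx) {
  m <- pres[, order_idx, drop = FALSE]
  cum <- m
  if (ncol(m) > 1L) {
    for (i in 2:ncol(m)) cum[, i] <- cum[, i - 1L] + m[, i]
  }
  steps <- seq_len(ncol(m))
  list(pan = unname(colSums(cum > 0L)),
       core = vapply(steps, function(i) sum(cum[, i] == i), numeric(1)))
}

#' Core/pan-genome accumulation curve
#'
#' At step i, the pan size is the number of families present in at least one
#' of the first i strains and the core size the number present in all i.
#' With `permutations >= 1`, strain orders are randomized and per-step means
#' and 2.5/97.5% quantiles reported.
#'
#' @param families Family tibble from [build_families()].
#' @param order Strain order (default: order of appearance in `families`).
#' @param permutations Number of random strain orders (0 = use `order`).
#' @param seed Seed for the permutation draw.
#' @return A `pan_core_curve` object; its `data` tibble has one row per step.
#' @export
pan_genome_curve <- function(families, order = NULL, permutations = 0L,
                             seed = 1L) {
  strains <- unique(families$strain_id)
  if (!length(strains)) abort("no strains in family table")
  pres <- table(families$family_id, families$strain_id)
  pres <- (pres > 0L) * 1L
  pres <- pres[, strains, drop = FALSE]
  if (permutations == 0L) {
    ord <- order %||% strains
    if (!setequal(ord, strains)) abort("order must contain each strain exactly once")
    cv <- curve_for_order(pres, match(ord, colnames(pres)))
    data <- tibble(step = seq_along(ord), strain = ord,
                   core = cv$core, pan = cv$pan)
  } else {
    if (permutations < 1L) abort("permutations must be >= 1 under the permuted policy")
    set.seed(seed)
    pans <- matrix(NA_real_, permutations, length(strains))
    cores <- matrix(NA_real_, permutations, length(strains))
    for (p in seq_len(permutations)) {
      cv <- curve_for_order(pres, sample.int(length(strains)))
      pans[p, ] <- cv$pan
      cores[p, ] <- cv$core
    }
    data <- tibble(
      step = seq_along(strains),
      core = colMeans(cores),
      core_lo = apply(cores, 2, quantile, 0.025),
      core_hi = apply(cores, 2, quantile, 0.975),
      pan = colMeans(pans),
      pan_lo = apply(pans, 2, quantile, 0.025),
      pan_hi = apply(pans, 2, quantile, 0.975)
    )
  }
  structure(list(data = data, strains = strains,
                 permuted = permutations > 0L,
                 n_permutations = as.integer(permutations)),
            class = "pan_core_curve")
}

#' @export
print.pan_core_curve <- function(x, ...) {
  cat(sprintf("<pan_core_curve> %d strains%s\n", length(x$strains),
              if (x$permuted) sprintf(", %d permutations", x$n_permutations)
              else ""))
  print(x$data, n = 5)
  invisible(x)
}

#' @export
tidy.pan_core_curve <- function(x, ...) x$data

#' @rdname pan_genome_curve
#' @param object,x A `pan_core_curve`.
#' @param ... Unused.
#' @export
autoplot.pan_core_curve <- function(object, ...) {
  d <- object$data |>
    tidyr::pivot_longer(dplyr::any_of(c("core", "pan")),
                        names_to = "component", values_to = "families")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$families,
                                       colour = .data$component)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "strains added", y = "gene families",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (object$permuted) {
    ribbon <- object$data |>
      tidyr::pivot_longer(dplyr::any_of(c("core", "pan")),
                          names_to = "component", values_to = "families") |>
      mutate(lo = ifelse(.data$component == "core", object$data$core_lo[.data$step],
                         object$data$pan_lo[.data$step]),
             hi = ifelse(.data$component == "core", object$data$core_hi[.data$step],
                         object$data$pan_hi[.data$step]))
    p <- p + ggplot2::geom_ribbon(
      data = ribbon,
      ggplot2::aes(ymin = .data$lo, ymax = .data$hi, fill = .data$component),
      alpha = 0.15, colour = NA
    ) + ggplot2::labs(fill = NULL)
  }
  p
}

#' Heaps-style openness of a pan-genome curve
#'
#' Fits `log(pan) ~ log(step)` on the (mean) accumulation curve; the slope
#' gamma estimates the Heaps exponent.  A population whose pan curve is still
#' adding genes at the final step with gamma < 1 is classified "open"; a
#' plateaued (or constant) curve is "closed".
#'
#' @param curve A `pan_core_curve` (permuted curves use the per-step mean).
#' @param rate_tol New genes per strain at the final step below which the
#'   curve counts as plateaued (default 0.5).
#' @return An `openness_fit` with `gamma`, `new_gene_rate`, `classification`
#'   ("open"/"closed"), and fit residuals; see [tidy()]/[glance()].
#' @export
openness_index <- function(curve, rate_tol = 0.5) {
  stopifnot(inherits(curve, "pan_core_curve"))
  d <- curve$data
  if (nrow(d) < 3L) abort("openness_index requires a curve over >= 3 strains")
  pan <- d$pan
  final_rate <- pan[length(pan)] - pan[length(pan) - 1L]
  if (max(pan) - min(pan) < .Machine$double.eps^0.5) {
    fit <- NULL
    gamma <- NA_real_
    res <- rep(0, length(pan))
  } else {
    fit <- lm(log(pan) ~ log(seq_along(pan)))
    gamma <- unname(coef(fit)[2L])
    res <- unname(residuals(fit))
  }
  classification <- if (final_rate < rate_tol || (!is.na(gamma) && gamma <= 0)) {
    "closed"
  } else {
    "open"
  }
  structure(list(gamma = gamma, new_gene_rate = final_rate,
                 classification = classification, residuals = res,
                 n_strains = nrow(d)),
            class = "openness_fit")
}

#' @export
print.openness_fit <- function(x, ...) {
  cat(sprintf("<openness_fit> %s (gamma = %s, final new-gene rate = %.2f)\n",
              x$classification,
              if (is.na(x$gamma)) "undefined" else sprintf("%.3f", x$gamma),
              x$new_gene_rate))
  invisible(x)
}

#' @export
glance.openness_fit <- function(x, ...) {
  tibble(gamma = x$gamma, new_gene_rate = x$new_gene_rate,
         classification = x$classification,
         rss = sum(x$residuals^2), n_strains = x$n_strains)
}

#' @export
tidy.openness_fit <- function(x, ...) {
  tibble(term = c("gamma", "new_gene_rate"),
         estimate = c(x$gamma, x$new_gene_rate))
}
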