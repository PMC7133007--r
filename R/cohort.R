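# Cohort-level genotype-diversity statistics: per-subject genotype counts by
# group, group distributions, and Wilcoxon rank-sum comparisons.

COHORT_GROUPS <- c("Children", "Students", "Seniors", "CRC")

#' Load a per-subject genotype table
#'
#' Reads a TSV with columns `group`, `subject_id`, `sex`, `age`,
#' `n_genotypes`, `n_isolates` and validates every row.  The default path is
#' the packaged table of 185 subjects in four groups (68 preschool children,
#' 87 university students, 15 longevity-village seniors, 15 colorectal
#' cancer patients; 16 colonies analyzed per senior, 12 otherwise).
#'
#' @param path TSV path; defaults to the packaged table.
#' @return A validated tibble of subject records.
#' @export
#' @examples
#' cohort <- load_cohort()
#' dplyr::count(cohort, group)
load_cohort <- function(path = colidiv_example("table1_cohort.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("group", "subject_id", "sex", "age", "n_genotypes", "n_isolates")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    abort(paste0("cohort table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad_group <- setdiff(unique(tab$group), COHORT_GROUPS)
  if (length(bad_group)) {
    abort(sprintf("unknown group '%s'", bad_group[1]))
  }
  bad <- which(tab$n_genotypes < 1L | tab$n_genotypes > tab$n_isolates)
  if (length(bad)) {
    abort(sprintf(
      "subject '%s': n_genotypes (%d) outside [1, n_isolates = %d]",
      tab$subject_id[bad[1]], tab$n_genotypes[bad[1]], tab$n_isolates[bad[1]]
    ))
  }
  as_tibble(tab) |>
    mutate(group = factor(.data$group, COHORT_GROUPS))
}

#' Total number of isolates in a cohort
#'
#' @param records Cohort tibble from [load_cohort()].
#' @return Integer sum of `n_isolates`.
#' @export
total_isolates <- function(records) {
  if (!nrow(records)) return(0L)
  sum(records$n_isolates)
}

#' Genotype-count distribution by group
#'
#' Tabulates, per group, the percentage of subjects carrying one, two, ...
#' up to `top` or more genotypes.
#'
#' @param records Cohort tibble.
#' @param group Optional single group to restrict to.
#' @param top Counts at or above `top` are pooled into one category.
#' @return A tibble (`group`, `category`, `n`, `pct`); percentages sum to
#'   100 within each group.
#' @export
genotype_distribution <- function(records, group = NULL, top = 5L) {
  if (!is.null(group)) {
    if (!group %in% records$group) abort(sprintf("group '%s' not present", group))
    records <- filter(records, .data$group == !!group)
  }
  levels_cat <- c(as.character(seq_len(top - 1L)), paste0("≥", top))
  records |>
    mutate(category = ifelse(.data$n_genotypes >= top, paste0("≥", top),
                             as.character(.data$n_genotypes)),
           category = factor(.data$category, levels_cat)) |>
    group_by(.data$group, .data$category, .drop = FALSE) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' @rdname genotype_distribution
#' @param object A cohort tibble (as from [load_cohort()]).
#' @param ... Passed to `genotype_distribution()`.
#' @export
plot_genotype_distribution <- function(object, ...) {
  d <- genotype_distribution(object, ...)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~group, nrow = 1) +
    ggplot2::labs(x = "genotypes per subject", y = "% of subjects") +
    ggplot2::theme_minimal()
}

# exact two-sided permutation p-value for the rank-sum of group a,
# enumerating all assignments of the pooled values to group a
rank_sum_exact <- function(r, n_a) {
  n <- length(r)
  m <- min(n_a, n - n_a)
  idx <- combn(n, m)
  sums <- colSums(matrix(r[idx], nrow = m))
  w_all <- if (m == n_a) sums else sum(r) - sums
  mu <- n_a * (n + 1) / 2
  w_obs <- sum(r[seq_len(n_a)])
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# normal approximation with mid-ranks, tie-corrected variance and
# continuity correction
rank_sum_approx <- function(r, n_a) {
  n <- length(r)
  n_b <- n - n_a
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  ties <- table(r)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(w = w, p = 1))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(w = w, p = min(1, 2 * pnorm(-abs(z))))
}

#' Wilcoxon rank-sum test on genotype counts
#'
#' Two-sided two-sample rank-sum test with mid-ranks.  `"exact"` enumerates
#' the permutation null (all assignments of the pooled values to the two
#' groups) and is the reference in the presence of heavy ties; `"approx"`
#' uses the normal approximation with tie-corrected variance and continuity
#' correction; `"auto"` (default) picks exact when the enumeration has at
#' most `exact_limit` assignments.
#'
#' @param a,b Numeric vectors (e.g. per-subject genotype counts).
#' @param mode `"auto"`, `"exact"`, or `"approx"`.
#' @param exact_limit Largest enumeration size `auto`/`exact` will attempt.
#' @return A `rank_sum_test`: statistic `W` (rank sum of `a`), two-sided
#'   `p_value`, sample sizes, and the method used.  See [tidy()]/[glance()].
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 1, 1), c(2, 2, 2), mode = "exact")
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "approx"),
                              exact_limit = 2e5) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  r <- rank(c(a, b))
  n_a <- length(a); n <- length(r)
  n_comb <- choose(n, min(n_a, n - n_a))
  if (mode == "auto") {
    mode <- if (n_comb <= exact_limit) "exact" else "approx"
  }
  if (mode == "exact" && n_comb > exact_limit) {
    abort(sprintf(
      "exact enumeration needs %.3g assignments (limit %.3g); use approx",
      n_comb, exact_limit
    ))
  }
  if (mode == "exact") {
    p <- rank_sum_exact(r, n_a)
    w <- sum(r[seq_len(n_a)])
  } else {
    ap <- rank_sum_approx(r, n_a)
    p <- ap$p; w <- ap$w
  }
  structure(list(
    statistic = w, p_value = p, n_a = n_a, n_b = n - n_a,
    method = if (mode == "exact") "exact permutation"
             else "normal approximation, tie-corrected, continuity-corrected"
  ), class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s)\nW = %g, n = %d + %d, p = %.4g\n",
              x$method, x$statistic, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n_a = x$n_a, n_b = x$n_b, method = x$method)
}

#' @export
glance.rank_sum_test <- function(x, ...) tidy(x)

#' All pairwise group comparisons of genotype counts
#'
#' One Wilcoxon rank-sum test per unordered pair of groups.  No multiplicity
#' adjustment is applied by default; Holm adjustment is available.
#'
#' @param records Cohort tibble.
#' @param mode Test mode, as in [wilcoxon_rank_sum()].
#' @param adjust `"none"` (default) or `"holm"`.
#' @return A tibble with one row per pair: sizes, `statistic`, `p_value`
#'   (and `p_adj` when adjusted), `method`.
#' @export
all_group_comparisons <- function(records, mode = "auto", adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- if (is.factor(records$group)) {
    intersect(levels(records$group), unique(as.character(records$group)))
  } else {
    unique(records$group)
  }
  if (length(groups) < 2L) abort("need >= 2 groups")
  pairs <- combn(groups, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    ga <- pairs[1L, i]; gb <- pairs[2L, i]
    xa <- records$n_genotypes[records$group == ga]
    xb <- records$n_genotypes[records$group == gb]
    fit <- wilcoxon_rank_sum(xa, xb, mode = mode)
    tibble(group_a = ga, group_b = gb, n_a = fit$n_a, n_b = fit$n_b,
           statistic = fit$statistic, p_value = fit$p_value,
           method = fit$method)
  })
  res <- bind_rows(out)
  if (adjust == "holm") res$p_adj <- stats::p.adjust(res$p_value, "holm")
  res
}
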