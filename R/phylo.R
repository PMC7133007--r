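# Concatenated single-copy-core supermatrix, pairwise distances, and a
# neighbor-joining tree with column-bootstrap supports.

#' Concatenate single-copy core families into a supermatrix
#'
#' Uses only families present in every strain with exactly one member per
#' strain.  Within a family, members of equal length are stacked directly;
#' unequal members are projected onto the longest member by ends-free global
#' alignment (insertions relative to the reference are dropped, deletions
#' become gaps), so all rows share the reference's column count.  Family
#' blocks are concatenated in lexicographic family order.
#'
#' @param genes Gene tibble.
#' @param families Family tibble from [build_families()].
#' @param strains Strain ids to include (default: all in `families`).
#' @return A `supermatrix`: named per-strain aligned sequences (`sequence_of`),
#'   a `blocks` tibble of 0-based half-open column ranges, and `columns`.
#' @export
concatenate_core <- function(genes, families,
                             strains = unique(families$strain_id)) {
  if (length(strains) < 3L) abort("concatenate_core requires >= 3 strains")
  fs <- family_summary(families |> filter(.data$strain_id %in% strains))
  keep <- fs$family_id[fs$n_strains == length(strains) & fs$is_single_copy]
  if (!length(keep)) abort("no single-copy families present in all strains")
  keep <- sort(keep)
  seq_tbl <- families |>
    filter(.data$family_id %in% keep, .data$strain_id %in% strains) |>
    inner_join(genes, by = c("gene_id", "strain_id"))

  rows <- setNames(vector("list", length(strains)), strains)
  for (s in strains) rows[[s]] <- character(length(keep))
  blocks <- integer(length(keep))
  for (fi in seq_along(keep)) {
    fam <- seq_tbl |> filter(.data$family_id == keep[fi])
    fam <- fam[match(strains, fam$strain_id), ]
    seqs <- setNames(fam$sequence, strains)
    if (length(unique(nchar(seqs))) == 1L) {
      aligned <- seqs
    } else {
      aligned <- star_align(seqs)
    }
    blocks[fi] <- nchar(aligned[[1L]])
    for (s in strains) rows[[s]][fi] <- aligned[[s]]
  }
  ends <- cumsum(blocks)
  structure(list(
    strains = strains,
    sequence_of = vapply(rows, paste, character(1), collapse = ""),
    blocks = tibble(family_id = keep,
                    start = c(0L, head(ends, -1L)),
                    end = ends),
    columns = sum(blocks)
  ), class = "supermatrix")
}

# Project all member sequences onto the coordinates of the longest member.
star_align <- function(seqs) {
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  out <- seqs
  for (i in seq_along(seqs)) {
    if (i == ref_i || seqs[[i]] == ref) {
      out[[i]] <- if (i == ref_i) ref else pad_to_ref(seqs[[i]], ref)
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(ref),
      type = "overlap", substitutionMatrix = align_scoring(),
      gapOpening = 5, gapExtension = 1
    )
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]]
    pr <- strsplit(as.character(Biostrings::subject(aln)), "")[[1L]]
    keep <- pr != "-"
    body <- paste(pa[keep], collapse = "")
    lead <- Biostrings::start(Biostrings::subject(aln)) - 1L
    trail <- nchar(ref) - Biostrings::end(Biostrings::subject(aln))
    out[[i]] <- paste0(strrep("-", lead), body, strrep("-", trail))
  }
  out
}

pad_to_ref <- function(s, ref) {
  if (nchar(s) == nchar(ref)) s else paste0(s, strrep("-", nchar(ref) - nchar(s)))
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d strains x %d columns (%d family blocks)\n",
              length(x$strains), x$columns, nrow(x$blocks)))
  invisible(x)
}

#' Pairwise distances from a supermatrix
#'
#' Per pair, columns where either sequence carries a gap or ambiguity are
#' deleted (pairwise deletion); p is the mismatch fraction over the
#' remaining columns.  The JC69 model applies the usual
#' \eqn{-\frac{3}{4}\ln(1 - \frac{4p}{3})} correction.
#'
#' @param sm A `supermatrix`.
#' @param model `"p"` (default) or `"JC69"`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(sm, model = c("p", "JC69")) {
  model <- match.arg(model)
  stopifnot(inherits(sm, "supermatrix"))
  n <- length(sm$strains)
  if (n < 2L) abort("distance_matrix requires >= 2 strains")
  chars <- do.call(rbind, strsplit(unname(sm$sequence_of), ""))
  valid <- matrix(chars %in% DNA_BASES, nrow = n)
  d <- matrix(0, n, n, dimnames = list(sm$strains, sm$strains))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      m <- sum(ok)
      if (m == 0L) {
        abort(sprintf("no comparable columns between '%s' and '%s'",
                      sm$strains[i], sm$strains[j]))
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / m
      if (model == "JC69") {
        if (p >= 0.75) {
          abort(sprintf("p-distance %.3f between '%s' and '%s' exceeds the JC69 domain",
                        p, sm$strains[i], sm$strains[j]))
        }
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion.  Ties in Q
#' are broken deterministically by the lowest index pair.  Negative branch
#' length estimates are clamped to zero and flagged via
#' `attr(tree, "clamped")`.  On additive (tree-metric) inputs the generating
#' tree is recovered exactly.
#'
#' @param d Symmetric non-negative distance matrix with labelled rows.
#' @return An unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-12) abort("d must be symmetric")
  if (any(d < 0)) abort("d must be non-negative")
  n <- nrow(d)
  if (n < 3L) abort("nj_tree requires >= 3 taxa")
  labels <- rownames(d) %||% sprintf("t%d", seq_len(n))
  frag <- labels                       # newick fragment per active cluster
  D <- d
  clamped <- FALSE
  bl <- function(v) {
    if (v < 0) clamped <<- TRUE
    format(max(v, 0), digits = 17, scientific = FALSE, trim = TRUE)
  }
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    best <- c(1L, 2L); best_q <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        if (Q[i, j] < best_q - 1e-12) {
          best_q <- Q[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(vi), frag[j], bl(vj))
    others <- setdiff(seq_len(r), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- rbind(cbind(D[others, others, drop = FALSE], dnew),
                c(dnew, 0))
    frag <- c(frag[others], newfrag)
    rownames(D2) <- colnames(D2) <- NULL
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], bl(v1), frag[2], bl(v2), frag[3], bl(v3))
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples supermatrix columns with replacement, rebuilds the NJ tree per
#' replicate, and reports the percentage of replicates containing each
#' internal bipartition of the original tree as internal node labels.
#'
#' @param sm A `supermatrix`.
#' @param n_replicates Number of bootstrap replicates (0 = no supports).
#' @param seed RNG seed; identical seeds give identical supports.
#' @param model Distance model, as in [distance_matrix()].
#' @return The original NJ `phylo`, with `node.label` percentages when
#'   `n_replicates > 0`.
#' @export
bootstrap_support <- function(sm, n_replicates = 100L, seed = 1L,
                              model = c("p", "JC69")) {
  model <- match.arg(model)
  if (n_replicates < 0L) abort("n_replicates must be >= 0")
  tree <- nj_tree(distance_matrix(sm, model))
  if (n_replicates == 0L) return(tree)
  set.seed(seed)
  chars <- do.call(rbind, strsplit(unname(sm$sequence_of), ""))
  rownames(chars) <- sm$strains
  boots <- vector("list", n_replicates)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(chars), replace = TRUE)
    sub <- sm
    sub$sequence_of <- setNames(
      apply(chars[, cols, drop = FALSE], 1L, paste, collapse = ""),
      sm$strains
    )
    sub$columns <- length(cols)
    boots[[b]] <- nj_tree(distance_matrix(sub, model))
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- formatC(100 * counts / n_replicates,
                             format = "f", digits = 1)
  tree
}

#' Write a supermatrix to FASTA and relaxed PHYLIP
#'
#' @param sm A `supermatrix`.
#' @param fasta,phylip Optional output paths (skipped when `NULL`).
#' @export
write_supermatrix <- function(sm, fasta = NULL, phylip = NULL) {
  if (!is.null(fasta)) {
    writeLines(as.vector(rbind(paste0(">", sm$strains),
                               unname(sm$sequence_of))), fasta)
  }
  if (!is.null(phylip)) {
    writeLines(c(sprintf("%d %d", length(sm$strains), sm$columns),
                 sprintf("%s  %s", sm$strains, unname(sm$sequence_of))),
               phylip)
  }
  invisible(NULL)
}
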