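# In-silico macro-restriction digestion and gel band-pattern genotyping.
# I-CeuI fragment counts track rRNA operon number; CTAG six-cutters (XbaI,
# AvrII/BlnI, SpeI, NheI) cut rarely and give lineage-diagnostic patterns.

#' Built-in restriction enzymes
#'
#' The I-CeuI entry uses the canonical 26-bp homing-site sequence; the CTAG
#' six-cutters are palindromic.  The cut offset is the 0-based position of
#' the cut within the motif on the top strand.
#'
#' @return A tibble: `name`, `motif` (IUPAC), `cut_offset`.
#' @export
restriction_enzymes <- function() {
  tibble(
    name = c("I-CeuI", "XbaI", "AvrII", "SpeI", "NheI"),
    motif = c("TAACTATAACGGTCCTAAGGTAGCGA",
              "TCTAGA", "CCTAGG", "ACTAGT", "GCTAGC"),
    cut_offset = c(18L, 1L, 1L, 1L, 1L)
  )
}

resolve_enzyme <- function(enzyme) {
  if (is.character(enzyme) && length(enzyme) == 1L) {
    tab <- restriction_enzymes()
    row <- tab[tab$name == enzyme, ]
    if (!nrow(row)) abort(sprintf("unknown enzyme '%s'", enzyme))
    return(as.list(row))
  }
  enzyme <- as.list(enzyme)
  stopifnot(all(c("name", "motif", "cut_offset") %in% names(enzyme)))
  if (nchar(enzyme$motif) < 4L) abort("enzyme motif must be >= 4 bp")
  enzyme
}

iupac_palindromic <- function(motif) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  identical(rc, motif)
}

# 0-based cut coordinates of an enzyme on a genome; both strands for
# non-palindromic motifs; origin-spanning matches included when circular.
cut_sites <- function(genome, circular, enzyme) {
  L <- nchar(enzyme$motif)
  glen <- nchar(genome)
  scan_seq <- if (circular && glen > L) {
    paste0(genome, substr(genome, 1L, L - 1L))
  } else {
    genome
  }
  subj <- Biostrings::DNAString(scan_seq)
  fwd <- Biostrings::start(
    Biostrings::matchPattern(Biostrings::DNAString(enzyme$motif), subj,
                             fixed = FALSE)
  )
  fwd <- fwd[fwd <= glen]
  cuts <- (fwd - 1L + enzyme$cut_offset) %% glen
  if (!iupac_palindromic(enzyme$motif)) {
    rcm <- Biostrings::reverseComplement(Biostrings::DNAString(enzyme$motif))
    rev <- Biostrings::start(Biostrings::matchPattern(rcm, subj, fixed = FALSE))
    rev <- rev[rev <= glen]
    # cut on the top strand mirrors the offset from the motif's other end
    cuts <- c(cuts, (rev - 1L + (L - enzyme$cut_offset)) %% glen)
  }
  sort(unique(as.integer(cuts)))
}

#' In-silico restriction digest of a genome
#'
#' Finds all motif matches (IUPAC-aware; both strands for non-palindromic
#' motifs; origin-spanning matches included for circular molecules) and
#' returns the inter-cut fragment sizes.  On a circular molecule the
#' fragment count equals the cut count and fragment sizes sum exactly to the
#' genome length; a linear molecule yields one more fragment than cuts.
#'
#' @param genome Nucleotide string.
#' @param circular Logical topology flag.
#' @param enzyme Enzyme name (see [restriction_enzymes()]) or a list with
#'   `name`, `motif`, `cut_offset`.
#' @param isolate_id Optional label carried into the profile.
#' @return A `digest_profile`: `fragment_sizes` (sorted), `sites` (0-based
#'   cut coordinates), `topology`, `uncut` flag, `genome_length`.
#' @export
digest <- function(genome, circular = TRUE, enzyme = "XbaI",
                   isolate_id = NA_character_) {
  if (!nzchar(genome)) abort("digest requires a non-empty genome")
  enzyme <- resolve_enzyme(enzyme)
  glen <- nchar(genome)
  cuts <- cut_sites(genome, circular, enzyme)
  if (circular) {
    frags <- if (length(cuts) == 0L) glen
             else if (length(cuts) == 1L) glen
             else c(diff(cuts), glen - cuts[length(cuts)] + cuts[1L])
  } else {
    frags <- diff(c(0L, cuts, glen))
  }
  structure(list(
    isolate_id = isolate_id,
    enzyme = enzyme$name,
    fragment_sizes = sort(as.integer(frags)),
    sites = cuts,
    topology = if (circular) "circular" else "linear",
    uncut = circular && length(cuts) == 0L,
    genome_length = glen
  ), class = "digest_profile")
}

#' @export
print.digest_profile <- function(x, ...) {
  cat(sprintf("<digest_profile> %s/%s: %d fragment(s)%s, %s bp total\n",
              x$isolate_id, x$enzyme, length(x$fragment_sizes),
              if (x$uncut) " (uncut)" else "",
              format(sum(x$fragment_sizes), big.mark = ",")))
  invisible(x)
}

#' Digest every genome in a tibble
#'
#' @param genomes Tibble with `strain_id` (or `isolate_id`), `genome`,
#'   `circular`.
#' @param enzyme As in [digest()].
#' @return A tibble with an `id` column and a `profile` list-column of
#'   `digest_profile` objects.
#' @export
digest_all <- function(genomes, enzyme = "XbaI") {
  id_col <- intersect(c("isolate_id", "strain_id"), names(genomes))[1]
  if (is.na(id_col)) abort("genomes need an isolate_id or strain_id column")
  tibble(
    id = genomes[[id_col]],
    profile = lapply(seq_len(nrow(genomes)), function(i) {
      digest(genomes$genome[i], genomes$circular[i], enzyme,
             isolate_id = genomes[[id_col]][i])
    })
  )
}

# merge ascending sizes whose relative difference <= tol into mean bands
merge_comigrating <- function(sizes, tol) {
  sizes <- sort(sizes)
  if (!length(sizes)) return(numeric(0))
  groups <- list()
  cur <- sizes[1L]
  for (s in sizes[-1L]) {
    if ((s - cur[length(cur)]) / s <= tol) {
      cur <- c(cur, s)
    } else {
      groups[[length(groups) + 1L]] <- cur
      cur <- s
    }
  }
  groups[[length(groups) + 1L]] <- cur
  vapply(groups, mean, numeric(1))
}

#' Gel-resolvable band profile from a digest
#'
#' Drops fragments outside the resolvable size window and greedily merges
#' ascending neighbours whose relative size difference is within the
#' co-migration tolerance into a single band at their mean size.
#'
#' @param d A `digest_profile`.
#' @param min_size,max_size Resolvable window in bp (defaults 10 kb and
#'   1.2 Mb, typical of PFGE run conditions).
#' @param comigration_tol Relative size difference below which neighbouring
#'   fragments co-migrate (default 0.02).
#' @return A `band_profile` with sorted band sizes.
#' @export
band_profile <- function(d, min_size = 1e4, max_size = 1.2e6,
                         comigration_tol = 0.02) {
  stopifnot(inherits(d, "digest_profile"))
  if (min_size > max_size) abort("min_size must not exceed max_size")
  if (comigration_tol < 0) abort("comigration_tol must be >= 0")
  keep <- d$fragment_sizes[d$fragment_sizes >= min_size &
                             d$fragment_sizes <= max_size]
  structure(list(
    isolate_id = d$isolate_id,
    enzyme = d$enzyme,
    bands = merge_comigrating(keep, comigration_tol)
  ), class = "band_profile")
}

#' @export
print.band_profile <- function(x, ...) {
  cat(sprintf("<band_profile> %s/%s: %d band(s)\n", x$isolate_id, x$enzyme,
              length(x$bands)))
  invisible(x)
}

# greedy size-ordered matching of two sorted band lists within relative tol
match_bands <- function(a, b, tol) {
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(a) && j <= length(b)) {
    rel <- abs(a[i] - b[j]) / max(a[i], b[j])
    if (rel <= tol) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  m
}

#' Dice similarity of two band profiles
#'
#' Greedy size-ordered matching of bands within a relative size tolerance;
#' Dice = 2 * matches / (bands in a + bands in b).  Two empty profiles count
#' as identical.
#'
#' @param a,b `band_profile` objects digested with the same enzyme.
#' @param match_tol Relative band-size matching tolerance (default 0.02).
#' @return A number in \[0, 1\].
#' @export
pattern_similarity <- function(a, b, match_tol = 0.02) {
  stopifnot(inherits(a, "band_profile"), inherits(b, "band_profile"))
  if (!identical(a$enzyme, b$enzyme)) {
    abort(sprintf("enzyme mismatch: '%s' vs '%s'", a$enzyme, b$enzyme))
  }
  na <- length(a$bands); nb <- length(b$bands)
  if (na + nb == 0L) return(1)
  2 * match_bands(sort(a$bands), sort(b$bands), match_tol) / (na + nb)
}

#' Assign PFGE genotypes by band-pattern identity
#'
#' Single-linkage clustering of isolates at pairwise pattern similarity at
#' or above `identity_threshold` (default 1: patterns must be
#' indistinguishable under the band-matching tolerance).  Genotype labels
#' run G1, G2, ... in order of first appearance.
#'
#' @param profiles List of `band_profile` objects (one enzyme).
#' @param identity_threshold Dice similarity at or above which two isolates
#'   share a genotype.
#' @param match_tol Band matching tolerance passed to
#'   [pattern_similarity()].
#' @return A `genotype_assignment`: tibble (`isolate_id`, `genotype`) and
#'   `n_genotypes`.
#' @export
assign_genotypes <- function(profiles, identity_threshold = 1,
                             match_tol = 0.02) {
  if (!length(profiles)) abort("assign_genotypes requires >= 1 profile")
  enz <- unique(vapply(profiles, function(p) p$enzyme, character(1)))
  if (length(enz) > 1L) {
    abort(paste0("profiles mix enzymes: ", paste(enz, collapse = ", ")))
  }
  n <- length(profiles)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (pattern_similarity(profiles[[i]], profiles[[j]], match_tol) >=
              identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lab <- match(comp, unique(comp))
  ids <- vapply(profiles, function(p) p$isolate_id, character(1))
  structure(list(
    assignment = tibble(isolate_id = ids, genotype = sprintf("G%d", lab)),
    n_genotypes = length(unique(lab))
  ), class = "genotype_assignment")
}

#' @export
print.genotype_assignment <- function(x, ...) {
  cat(sprintf("<genotype_assignment> %d genotype(s) over %d isolate(s)\n",
              x$n_genotypes, nrow(x$assignment)))
  invisible(x)
}

#' @export
tidy.genotype_assignment <- function(x, ...) x$assignment

#' @export
glance.genotype_assignment <- function(x, ...) {
  tibble(n_isolates = nrow(x$assignment), n_genotypes = x$n_genotypes)
}

#' Simulated mixed-culture gel lane
#'
#' The lane of a mixture of strains shows the union of the member bands,
#' re-merged under the co-migration tolerance.
#'
#' @param profiles Non-empty list of `band_profile` objects (one enzyme).
#' @param comigration_tol Co-migration tolerance for re-merging.
#' @return A `band_profile` for the mixture.
#' @export
mixture_lane <- function(profiles, comigration_tol = 0.02) {
  if (!length(profiles)) abort("mixture_lane requires >= 1 profile")
  enz <- unique(vapply(profiles, function(p) p$enzyme, character(1)))
  if (length(enz) > 1L) {
    abort(paste0("profiles mix enzymes: ", paste(enz, collapse = ", ")))
  }
  structure(list(
    isolate_id = paste0("mix(", paste(
      vapply(profiles, function(p) p$isolate_id, character(1)), collapse = "+"
    ), ")"),
    enzyme = enz,
    bands = merge_comigrating(
      unlist(lapply(profiles, function(p) p$bands)), comigration_tol
    )
  ), class = "band_profile")
}

#' Identify the surviving strain from an end-culture lane
#'
#' A candidate is compatible with the end lane when at least
#' `identity_threshold` of its bands appear in the lane (band containment
#' under the matching tolerance) — a lane showing the union of several
#' surviving strains is therefore compatible with each of them.  A unique
#' compatible candidate is the winner; otherwise the result is flagged
#' `"ambiguous"` (several compatible) or `"none"`.
#'
#' @param end `band_profile` of the end culture lane.
#' @param candidates List of >= 2 candidate `band_profile`s.
#' @param identity_threshold Minimum contained-band fraction (default 1).
#' @param match_tol Band matching tolerance.
#' @return A list: `status` (`"unique"`, `"ambiguous"`, `"none"`), `winner`
#'   (isolate id or `NA`), and a `scores` tibble with per-candidate
#'   containment and Dice similarity.
#' @export
match_end_culture <- function(end, candidates, identity_threshold = 1,
                              match_tol = 0.02) {
  if (length(candidates) < 2L) abort("match_end_culture requires >= 2 candidates")
  scores <- bind_rows(lapply(candidates, function(p) {
    if (!identical(p$enzyme, end$enzyme)) {
      abort(sprintf("enzyme mismatch: '%s' vs '%s'", p$enzyme, end$enzyme))
    }
    m <- match_bands(sort(p$bands), sort(end$bands), match_tol)
    tibble(isolate_id = p$isolate_id,
           containment = if (length(p$bands)) m / length(p$bands) else 1,
           dice = pattern_similarity(p, end, match_tol))
  }))
  compatible <- scores$isolate_id[scores$containment >= identity_threshold]
  status <- if (length(compatible) == 1L) "unique"
            else if (length(compatible) > 1L) "ambiguous"
            else "none"
  list(status = status,
       winner = if (status == "unique") compatible else NA_character_,
       scores = scores)
}

#' Plot band profiles as a virtual gel
#'
#' @param profiles List of `band_profile` objects.
#' @return A ggplot: one lane per profile, band size on a log axis.
#' @export
plot_virtual_gel <- function(profiles) {
  d <- bind_rows(lapply(profiles, function(p) {
    if (!length(p$bands)) return(NULL)
    tibble(lane = p$isolate_id, size = p$bands)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lane, y = .data$size)) +
    ggplot2::geom_point(shape = 95, size = 8, colour = "grey15") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "fragment size (bp)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write band profiles as a text virtual gel
#'
#' One lane per profile; bands listed largest to smallest.
#'
#' @param profiles List of `band_profile` objects.
#' @param path Output text file.
#' @export
write_virtual_gel <- function(profiles, path) {
  lines <- vapply(profiles, function(p) {
    sprintf("%-24s | %s", p$isolate_id,
            paste(format(round(sort(p$bands, decreasing = TRUE))),
                  collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
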