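# Internal sequence helpers shared by the simulator and the analysis modules.

DNA_BASES <- c("A", "C", "G", "T")

# Random nucleotide string, GC 0.5.
random_seq <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Per-site independent substitution: each site mutates with probability `rate`,
# uniformly to one of the three alternative bases (Jukes-Cantor style, no
# indels).  Returns the mutated string.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

# Disrupt every occurrence of `motif` in `seq` by flipping its middle base to a
# different base (deterministic given the RNG state).  Re-scans until clean so
# overlapping occurrences cannot survive.
scrub_motif <- function(seq, motif) {
  mid <- ceiling(nchar(motif) / 2)
  repeat {
    hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(seq)
    for (h in hits) {
      pos <- h + mid - 1L
      old <- substr(seq, pos, pos)
      substr(seq, pos, pos) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
}

check_dna <- function(sequence, ids) {
  bad <- grepl("[^ACGT]", sequence)
  if (any(bad)) {
    abort(sprintf(
      "sequence of gene '%s' contains characters outside A/C/G/T",
      ids[which(bad)[1]]
    ))
  }
  invisible(TRUE)
}

# Validate a gene table: tibble with gene_id, strain_id, sequence.
check_gene_table <- function(genes) {
  need <- c("gene_id", "strain_id", "sequence")
  missing <- setdiff(need, names(genes))
  if (length(missing)) {
    abort(paste0("gene table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  dup <- genes |>
    dplyr::count(.data$strain_id, .data$gene_id) |>
    filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("gene id '%s' duplicated within strain '%s'",
                  dup$gene_id[1], dup$strain_id[1]))
  }
  invisible(TRUE)
}

`%e%` <- function(x, y) if (length(x) == 0L) y else x

# sample() that never falls into the 1:n trap on length-1 vectors.
resample <- function(x, size = length(x), replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}
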