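#' Simulation configuration for a synthetic commensal population
#'
#' Describes the generative model used throughout the package's tests and
#' examples: a small number of deeply diverged clonal lineages (discrete
#' clusters, not a continuum), each carrying every ancestral core gene mutated
#' independently at `divergence_between` substitutions/site, plus its own
#' accessory genes drawn without replacement from a shared pool of unrelated
#' random genes.  Genomes are circular by default, carry `n_rrn_operons`
#' copies of a conserved 23S-like rRNA cassette embedding the 26-bp I-CeuI
#' homing site, and are assembled so that XbaI (TCTAGA) sites occur at a
#' controlled, PFGE-like density.
#'
#' The cohort-design defaults mirror the study design the package's cohort
#' statistics address: four participant groups (Children, Students, Seniors,
#' CRC) with 68/87/15/15 subjects, 16 colonies sampled per Senior and 12 per
#' subject otherwise, and per-group genotype-count distributions taken
#' empirically from the packaged per-subject genotype table.
#'
#' @param n_lineages Number of lineages (discrete clusters) to emit.
#' @param core_size Number of ancestral core genes shared by all lineages.
#' @param accessory_pool_size Size of the pool of unrelated accessory genes.
#' @param gene_length_range Integer pair; gene lengths are uniform in this
#'   range (bp).
#' @param divergence_between Substitutions/site applied independently on each
#'   lineage's branch from the ancestor, in \[0, 0.2\].
#' @param divergence_within Substitutions/site applied per isolate within a
#'   lineage (default 0: clonal isolates are identical).
#' @param gain_rate,loss_rate Expected accessory gene gains/losses per lineage
#'   (Poisson); losses remove a subset of that lineage's own gains.
#' @param n_rrn_operons rRNA operon copies per genome (each carries one I-CeuI
#'   site).
#' @param genome_length Genome size in bp.
#' @param circular Logical; circular chromosome topology.
#' @param xbaI_site_range Integer pair; target range for the number of XbaI
#'   sites injected into intergenic filler (gene-borne sites come on top).
#' @param n_subjects_per_group Named integer vector, subjects per group.
#' @param genotypes_per_subject_distribution Optional named list mapping each
#'   group to a probability table over genotype counts (names = counts).  When
#'   `NULL`, the empirical distribution of the packaged genotype table is used
#'   for groups with matching names.
#' @param colonies_per_subject Named integer vector (or single integer) of
#'   colonies sampled per subject in each group.
#' @param seed Master seed; identical seed and configuration give
#'   byte-identical output.
#' @return A `colidiv_sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_lineages = 3, core_size = 20, seed = 1)
sim_config <- function(n_lineages = 16L,
                       core_size = 100L,
                       accessory_pool_size = 6000L,
                       gene_length_range = c(500L, 1500L),
                       divergence_between = 0.03,
                       divergence_within = 0,
                       gain_rate = 300,
                       loss_rate = 0,
                       n_rrn_operons = 7L,
                       genome_length = 1000000L,
                       circular = TRUE,
                       xbaI_site_range = c(20L, 40L),
                       n_subjects_per_group = c(Children = 68L, Students = 87L,
                                                Seniors = 15L, CRC = 15L),
                       genotypes_per_subject_distribution = NULL,
                       colonies_per_subject = c(Children = 12L, Students = 12L,
                                                Seniors = 16L, CRC = 12L),
                       seed = 1L) {
  stopifnot(
    n_lineages >= 1L, core_size >= 1L, accessory_pool_size >= 0L,
    length(gene_length_range) == 2L,
    gene_length_range[1] >= 50L,
    gene_length_range[1] <= gene_length_range[2],
    divergence_between >= 0, divergence_between <= 0.2,
    divergence_within >= 0,
    gain_rate >= 0, loss_rate >= 0,
    n_rrn_operons >= 1L, genome_length >= 1000L,
    length(xbaI_site_range) == 2L,
    all(n_subjects_per_group >= 0L),
    all(colonies_per_subject >= 1L),
    is.numeric(seed), length(seed) == 1L
  )
  if (divergence_between < divergence_within) {
    abort("divergence_between must be >= divergence_within")
  }
  if (genome_length <= n_rrn_operons * RRN_CASSETTE_LENGTH) {
    abort("genome_length too small for the requested number of rRNA operons")
  }
  if (is.null(names(n_subjects_per_group))) {
    abort("n_subjects_per_group must be a named vector")
  }
  if (length(colonies_per_subject) == 1L && is.null(names(colonies_per_subject))) {
    colonies_per_subject <- setNames(
      rep(as.integer(colonies_per_subject), length(n_subjects_per_group)),
      names(n_subjects_per_group)
    )
  }
  structure(list(
    n_lineages = as.integer(n_lineages),
    core_size = as.integer(core_size),
    accessory_pool_size = as.integer(accessory_pool_size),
    gene_length_range = as.integer(gene_length_range),
    divergence_between = divergence_between,
    divergence_within = divergence_within,
    gain_rate = gain_rate,
    loss_rate = loss_rate,
    n_rrn_operons = as.integer(n_rrn_operons),
    genome_length = as.integer(genome_length),
    circular = isTRUE(circular),
    xbaI_site_range = as.integer(xbaI_site_range),
    n_subjects_per_group = n_subjects_per_group,
    genotypes_per_subject_distribution = genotypes_per_subject_distribution,
    colonies_per_subject = colonies_per_subject,
    seed = as.integer(seed)
  ), class = "colidiv_sim_config")
}

RRN_CASSETTE_LENGTH <- 2900L
ICEUI_MOTIF <- "TAACTATAACGGTCCTAAGGTAGCGA"
XBAI_MOTIF <- "TCTAGA"

#' Simulate diverged bacterial lineages with genomes and a truth set
#'
#' Emits one strain per lineage.  Core genes are present in every lineage,
#' mutated independently from a common ancestor at
#' `config$divergence_between`; accessory genes are unrelated random sequences
#' drawn without replacement from a shared pool, so homology search must find
#' no hits between accessory genes of different lineages.  Genomes interleave
#' rRNA cassettes (each with one I-CeuI homing site), the lineage's genes in
#' random order, and intergenic filler with a controlled XbaI site count.
#'
#' @param config A [sim_config()] object.
#' @param genomes Logical; assemble full genome sequences (needed only for
#'   in-silico digestion).
#' @return A `colidiv_population` list with elements `genes` (tibble:
#'   `gene_id`, `strain_id`, `sequence`), `genomes` (tibble: `strain_id`,
#'   `genome`, `circular`, or `NULL`), `truth` (list: `lineages`,
#'   `true_families` tibble, `true_tree` as `ape::phylo`), and `config`.
#' @export
#' @examples
#' pop <- simulate_lineages(sim_config(n_lineages = 2, core_size = 5,
#'                                     gain_rate = 2, accessory_pool_size = 10,
#'                                     genome_length = 40000, seed = 4),
#'                          genomes = FALSE)
#' pop$genes
simulate_lineages <- function(config, genomes = TRUE) {
  stopifnot(inherits(config, "colidiv_sim_config"))
  set.seed(config$seed)
  k <- config$n_lineages
  lineages <- sprintf("L%d", seq_len(k))

  glen <- function(n) {
    sample(seq(config$gene_length_range[1], config$gene_length_range[2]), n,
           replace = TRUE)
  }

  # Ancestral core genes (XbaI-free so genomic site density stays controlled).
  core_len <- glen(config$core_size)
  core_anc <- vapply(core_len, function(n) scrub_motif(random_seq(n), XBAI_MOTIF),
                     character(1))

  # Accessory pool: unrelated random genes, drawn without replacement.
  pool_len <- glen(config$accessory_pool_size)
  pool <- vapply(pool_len, function(n) scrub_motif(random_seq(n), XBAI_MOTIF),
                 character(1))
  pool_free <- seq_len(config$accessory_pool_size)

  # Conserved 23S-like cassette with one embedded I-CeuI homing site.
  cassette <- scrub_motif(random_seq(RRN_CASSETTE_LENGTH), XBAI_MOTIF)
  ins_at <- 1000L
  substr(cassette, ins_at, ins_at + nchar(ICEUI_MOTIF) - 1L) <- ICEUI_MOTIF

  genes_list <- vector("list", k)
  fam_list <- vector("list", k)
  genome_rows <- vector("list", k)

  for (j in seq_len(k)) {
    lid <- lineages[j]
    core_seq <- vapply(core_anc, mutate_seq, character(1),
                       rate = config$divergence_between, USE.NAMES = FALSE)
    core_ids <- sprintf("%s_C%04d", lid, seq_len(config$core_size))

    n_gain <- rpois(1L, config$gain_rate)
    if (n_gain > length(pool_free)) {
      abort(sprintf(
        "accessory pool exhausted: lineage %s requested %d genes but only %d remain",
        lid, n_gain, length(pool_free)
      ))
    }
    take <- if (n_gain > 0L) resample(pool_free, n_gain) else integer(0)
    pool_free <- setdiff(pool_free, take)
    n_loss <- min(rpois(1L, config$loss_rate), length(take))
    if (n_loss > 0L) take <- setdiff(take, resample(take, n_loss))
    acc_ids <- sprintf("%s_ACC%04d", lid, take)

    genes_list[[j]] <- tibble(
      gene_id = c(core_ids, acc_ids),
      strain_id = lid,
      sequence = c(core_seq, pool[take])
    )
    fam_list[[j]] <- tibble(
      gene_id = c(core_ids, acc_ids),
      family_id = c(sprintf("CORE%04d", seq_len(config$core_size)),
                    sprintf("ACC%04d", take))
    )
    if (genomes) {
      genome_rows[[j]] <- tibble(
        strain_id = lid,
        genome = assemble_genome(genes_list[[j]]$sequence, cassette, config),
        circular = config$circular
      )
    }
  }

  true_tree <- if (k >= 2L) {
    ape::read.tree(text = paste0(
      "(", paste(sprintf("%s:%g", lineages, config$divergence_between),
                 collapse = ","), ");"
    ))
  } else {
    ape::read.tree(text = sprintf("(%s:%g);", lineages, config$divergence_between))
  }

  structure(list(
    genes = bind_rows(genes_list),
    genomes = if (genomes) bind_rows(genome_rows) else NULL,
    truth = list(
      lineages = lineages,
      true_families = bind_rows(fam_list),
      true_tree = true_tree
    ),
    config = config
  ), class = "colidiv_population")
}

# Assemble a genome: n_rrn segments, each cassette + genes + scrubbed filler;
# then inject XbaI sites into filler to reach the configured density.
assemble_genome <- function(gene_seqs, cassette, config) {
  n_seg <- config$n_rrn_operons
  fixed <- n_seg * nchar(cassette) + sum(nchar(gene_seqs))
  filler_total <- config$genome_length - fixed
  if (filler_total < n_seg * 200L) {
    abort("genome_length too small to hold rRNA operons, genes and filler")
  }
  ord <- sample.int(length(gene_seqs))
  chunk <- if (length(ord)) {
    split(gene_seqs[ord], sort(rep_len(seq_len(n_seg), length(ord))))
  } else {
    rep(list(character(0)), n_seg)
  }
  alloc <- as.vector(stats::rmultinom(1L, filler_total - n_seg * 100L,
                                      rep(1 / n_seg, n_seg))) + 100L
  filler_spans <- vector("list", n_seg)
  parts <- character(n_seg)
  offset <- 0L
  for (s in seq_len(n_seg)) {
    fill <- scrub_motif(random_seq(alloc[s]), XBAI_MOTIF)
    seg <- paste0(cassette, paste(chunk[[min(s, length(chunk))]], collapse = ""),
                  fill)
    fill_start <- offset + nchar(seg) - nchar(fill) + 1L
    filler_spans[[s]] <- c(fill_start, offset + nchar(seg))
    parts[s] <- seg
    offset <- offset + nchar(seg)
  }
  genome <- paste(parts, collapse = "")

  present <- length(gregexpr(XBAI_MOTIF, genome, fixed = TRUE)[[1]])
  if (gregexpr(XBAI_MOTIF, genome, fixed = TRUE)[[1]][1] == -1L) present <- 0L
  target <- resample(seq(config$xbaI_site_range[1], config$xbaI_site_range[2]), 1L)
  need <- target - present
  if (need > 0L) {
    # Candidate positions inside filler, kept >= 6 bp apart.
    cand <- unlist(lapply(filler_spans, function(sp) {
      seq(sp[1], sp[2] - nchar(XBAI_MOTIF), by = 12L)
    }))
    pos <- resample(cand, min(need, length(cand)))
    for (p in pos) {
      substr(genome, p, p + nchar(XBAI_MOTIF) - 1L) <- XBAI_MOTIF
    }
  }
  genome
}

#' @export
print.colidiv_population <- function(x, ...) {
  cat(sprintf(
    "<colidiv_population> %d lineages, %d genes%s\n",
    length(x$truth$lineages), nrow(x$genes),
    if (is.null(x$genomes)) "" else sprintf(", genomes of %s bp",
                                            format(x$config$genome_length,
                                                   big.mark = ","))
  ))
  invisible(x)
}

#' Empirical genotype-count distribution of a cohort table
#'
#' @param records A cohort tibble as returned by [load_cohort()].
#' @param group Group label.
#' @return A named numeric vector of probabilities over genotype counts.
#' @export
empirical_genotype_distribution <- function(records, group) {
  x <- records$n_genotypes[records$group == group]
  if (!length(x)) abort(sprintf("no subjects in group '%s'", group))
  tab <- table(x)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Sample a host cohort from simulated lineages
#'
#' For each subject, draws a genotype count from the configured per-group
#' distribution, picks that many distinct lineages, and samples the subject's
#' colonies from them with every chosen lineage represented at least once —
#' so the truth genotype count always equals the number of distinct lineage
#' labels among the subject's isolates.
#'
#' @param population A `colidiv_population` from [simulate_lineages()].
#' @param config A [sim_config()]; defaults to the population's own.
#' @return A `colidiv_cohort_sim` list with `isolates` (tibble: `isolate_id`,
#'   `subject_id`, `group`, `lineage_id`), `subjects` (tibble with true
#'   genotype counts), and `genomes` (per-isolate genomes when
#'   `divergence_within > 0`, otherwise `NULL`; lineage genomes apply).
#' @export
sample_cohort <- function(population, config = population$config) {
  stopifnot(inherits(population, "colidiv_population"),
            inherits(config, "colidiv_sim_config"))
  set.seed((config$seed %% 1000000000L) + 1000003L)
  lineages <- population$truth$lineages
  groups <- names(config$n_subjects_per_group)

  dists <- config$genotypes_per_subject_distribution
  if (is.null(dists)) {
    tab <- load_cohort()
    known <- intersect(groups, unique(tab$group))
    if (length(known) < length(groups)) {
      abort(paste0(
        "no genotype-count distribution configured for group(s): ",
        paste(setdiff(groups, known), collapse = ", ")
      ))
    }
    dists <- lapply(setNames(known, known), empirical_genotype_distribution,
                    records = tab)
  }

  subj_rows <- list()
  iso_rows <- list()
  for (g in groups) {
    n_subj <- config$n_subjects_per_group[[g]]
    colonies <- config$colonies_per_subject[[g]]
    if (is.null(colonies)) abort(sprintf("no colonies_per_subject for group '%s'", g))
    dist_g <- dists[[g]]
    if (is.null(dist_g)) abort(sprintf("no genotype distribution for group '%s'", g))
    counts <- as.integer(names(dist_g))
    for (s in seq_len(n_subj)) {
      sid <- sprintf("%s_%03d", g, s)
      ng <- resample(counts, 1L, prob = dist_g)
      ng <- min(ng, colonies)
      if (ng > length(lineages)) {
        abort(sprintf(
          "subject %s requires %d genotypes but only %d lineages were simulated",
          sid, ng, length(lineages)
        ))
      }
      chosen <- resample(lineages, ng)
      assignment <- c(chosen, resample(chosen, colonies - ng, replace = TRUE))
      assignment <- resample(assignment)
      subj_rows[[sid]] <- tibble(subject_id = sid, group = g,
                                 n_isolates = colonies, n_genotypes_true = ng)
      iso_rows[[sid]] <- tibble(
        isolate_id = sprintf("%s_i%02d", sid, seq_len(colonies)),
        subject_id = sid, group = g, lineage_id = assignment
      )
    }
  }
  isolates <- bind_rows(iso_rows)

  iso_genomes <- NULL
  if (config$divergence_within > 0 && !is.null(population$genomes)) {
    lg <- setNames(population$genomes$genome, population$genomes$strain_id)
    iso_genomes <- isolates |>
      mutate(
        genome = vapply(lg[.data$lineage_id], mutate_seq, character(1),
                        rate = config$divergence_within, USE.NAMES = FALSE),
        circular = config$circular
      ) |>
      select("isolate_id", "genome", "circular")
  }

  structure(list(
    isolates = isolates,
    subjects = bind_rows(subj_rows),
    genomes = iso_genomes,
    config = config
  ), class = "colidiv_cohort_sim")
}

#' Materialize per-isolate gene tables for a sampled cohort
#'
#' Each isolate inherits its lineage's gene set; with
#' `divergence_within > 0`, genes are additionally mutated per isolate.
#'
#' @param cohort A `colidiv_cohort_sim` from [sample_cohort()].
#' @param population The `colidiv_population` the cohort was sampled from.
#' @param isolate_ids Optional subset of isolates.
#' @return A gene tibble (`gene_id`, `strain_id` = isolate id, `sequence`).
#' @export
isolate_gene_table <- function(cohort, population, isolate_ids = NULL) {
  iso <- cohort$isolates
  if (!is.null(isolate_ids)) iso <- filter(iso, .data$isolate_id %in% isolate_ids)
  d <- cohort$config$divergence_within
  out <- lapply(seq_len(nrow(iso)), function(i) {
    g <- filter(population$genes, .data$strain_id == iso$lineage_id[i])
    seqs <- if (d > 0) vapply(g$sequence, mutate_seq, character(1), rate = d,
                              USE.NAMES = FALSE) else g$sequence
    tibble(gene_id = paste0(iso$isolate_id[i], ".", g$gene_id),
           strain_id = iso$isolate_id[i], sequence = seqs)
  })
  bind_rows(out)
}

#' Write a simulated population to disk
#'
#' Writes one CDS multi-FASTA (`<strain>.ffn`) and one genome FASTA
#' (`<strain>.fna`, header carrying a `circular=` flag) per strain, the truth
#' family table as TSV, and a plain-text `manifest.cfg` with the resolved
#' configuration.
#'
#' @param population A `colidiv_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lid in population$truth$lineages) {
    g <- filter(population$genes, .data$strain_id == lid)
    cds <- Biostrings::DNAStringSet(setNames(g$sequence, g$gene_id))
    Biostrings::writeXStringSet(cds, file.path(dir, paste0(lid, ".ffn")))
    if (!is.null(population$genomes)) {
      row <- filter(population$genomes, .data$strain_id == lid)
      gn <- Biostrings::DNAStringSet(setNames(
        row$genome,
        sprintf("%s circular=%s", lid, tolower(as.character(row$circular)))
      ))
      Biostrings::writeXStringSet(gn, file.path(dir, paste0(lid, ".fna")))
    }
  }
  readr_write_tsv(population$truth$true_families,
                  file.path(dir, "truth_families.tsv"))
  cfg <- population$config
  scalar <- vapply(cfg, function(v) is.atomic(v) && length(v) == 1L, logical(1))
  lines <- c(
    sprintf("%s = %s", names(cfg)[scalar],
            vapply(cfg[scalar], as.character, character(1))),
    sprintf("%s = %s", names(cfg)[!scalar],
            vapply(cfg[!scalar], function(v) {
              paste(if (!is.null(names(v))) paste0(names(v), ":", unlist(v))
                    else unlist(v), collapse = ",")
            }, character(1)))
  )
  writeLines(lines, file.path(dir, "manifest.cfg"))
  invisible(dir)
}

#' Read per-strain CDS multi-FASTA files into a gene table
#'
#' @param dir Directory containing `<strain>.ffn` files.
#' @return A gene tibble (`gene_id`, `strain_id`, `sequence`).
#' @export
read_strain_cds <- function(dir) {
  files <- dir(dir, pattern = "\\.ffn$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no .ffn files under '%s'", dir))
  bind_rows(lapply(files, function(f) {
    x <- Biostrings::readDNAStringSet(f)
    tibble(gene_id = sub(" .*", "", names(x)),
           strain_id = sub("\\.ffn$", "", basename(f)),
           sequence = unname(as.character(x)))
  }))
}

#' Read per-strain genome FASTA files (with circular flag) into a tibble
#'
#' @param dir Directory containing `<strain>.fna` files.
#' @return A tibble (`strain_id`, `genome`, `circular`).
#' @export
read_strain_genomes <- function(dir) {
  files <- dir(dir, pattern = "\\.fna$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no .fna files under '%s'", dir))
  bind_rows(lapply(files, function(f) {
    x <- Biostrings::readDNAStringSet(f)
    tibble(strain_id = sub(" .*", "", names(x)[1]),
           genome = unname(as.character(x[[1]])),
           circular = grepl("circular=true", names(x)[1], fixed = TRUE))
  }))
}

# Minimal TSV writer (avoids a hard readr dependency in Imports).
readr_write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
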