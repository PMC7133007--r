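# One reproducible run: simulate -> homology -> pan/core -> boundaries ->
# tree -> PFGE genotyping -> cohort statistics, with a plain-text manifest.

#' Pipeline configuration
#'
#' Bundles per-stage parameters for [run_pipeline()].  Any subset of stages
#' can be enabled; stages consume the outputs of earlier ones, so enabling a
#' stage implies its prerequisites ran (the `stats` stage alone falls back
#' to the packaged genotype table).
#'
#' @param sim A [sim_config()]; its seed is the run's master seed.
#' @param stages Character vector out of `"simulate"`, `"homology"`,
#'   `"pancore"`, `"boundary"`, `"tree"`, `"pfge"`, `"stats"`.
#' @param min_identity,min_coverage Homology criterion bounds.
#' @param permutations Pan/core curve permutations.
#' @param boundary_threshold Identical-ratio clustering threshold.
#' @param bootstrap NJ bootstrap replicates.
#' @param tree_model Distance model for the tree stage.
#' @param enzyme PFGE enzyme name.
#' @param min_size,max_size,comigration_tol,match_tol Gel model parameters.
#' @param genotype_threshold Pattern-identity threshold for genotype calls.
#' @param stats_mode Wilcoxon mode for the stats stage.
#' @return A `colidiv_pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("simulate", "homology", "pancore",
                                       "boundary", "tree", "pfge", "stats"),
                            min_identity = 0.70, min_coverage = 0.70,
                            permutations = 20L,
                            boundary_threshold = 0.10,
                            bootstrap = 100L, tree_model = "p",
                            enzyme = "XbaI",
                            min_size = 1e4, max_size = 1.2e6,
                            comigration_tol = 0.02, match_tol = 0.02,
                            genotype_threshold = 1,
                            stats_mode = "auto") {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "colidiv_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writes every stage
#' output as plain text under `out_dir`, and finishes with a
#' `MANIFEST.txt` recording the resolved parameters and an MD5 checksum per
#' output file.  Reruns with the same configuration and seed are
#' byte-identical (manifest timestamp aside).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list of in-memory stage results plus the manifest
#'   path.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "colidiv_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_run <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
    say("stage %-9s %6.1fs", stage,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  res <- list()
  on <- function(s) s %in% config$stages

  if (on("simulate")) {
    res$population <- t_run("simulate", simulate_lineages(
      config$sim, genomes = on("pfge")
    ))
    res$cohort <- t_run("cohort", sample_cohort(res$population))
    write_population(res$population, file.path(out_dir, "population"))
    readr_write_tsv(res$cohort$isolates, file.path(out_dir, "isolates.tsv"))
    readr_write_tsv(res$cohort$subjects, file.path(out_dir, "subjects_truth.tsv"))
  }

  if (on("homology")) {
    res$hits <- t_run("homology", all_vs_all(
      res$population$genes,
      min_identity = config$min_identity, min_coverage = config$min_coverage
    ))
    res$families <- build_families(res$hits, res$population$genes)
    readr_write_tsv(res$hits, file.path(out_dir, "hits.tsv"))
    readr_write_tsv(res$families, file.path(out_dir, "families.tsv"))
  }

  if (on("pancore")) {
    res$curve <- t_run("pancore", pan_genome_curve(
      res$families, permutations = config$permutations,
      seed = config$sim$seed
    ))
    res$openness <- openness_index(res$curve)
    readr_write_tsv(res$curve$data, file.path(out_dir, "pan_core_curve.tsv"))
    readr_write_tsv(glance(res$openness), file.path(out_dir, "openness.tsv"))
  }

  if (on("boundary")) {
    res$ratios <- t_run("boundary", ratio_matrix(
      res$population$genes, res$families
    ))
    res$boundaries <- delineate_clusters(res$ratios, config$boundary_threshold)
    write_ratio_matrix(res$ratios, file.path(out_dir, "identical_ratio_pct.tsv"))
    readr_write_tsv(res$boundaries$clusters, file.path(out_dir, "clusters.tsv"))
  }

  if (on("tree")) {
    res$supermatrix <- t_run("tree", concatenate_core(
      res$population$genes, res$families
    ))
    res$tree <- bootstrap_support(res$supermatrix, config$bootstrap,
                                  seed = config$sim$seed,
                                  model = config$tree_model)
    ape::write.tree(res$tree, file.path(out_dir, "core_nj.nwk"))
    write_supermatrix(res$supermatrix,
                      fasta = file.path(out_dir, "supermatrix.fasta"),
                      phylip = file.path(out_dir, "supermatrix.phy"))
    readr_write_tsv(
      as.data.frame(distance_matrix(res$supermatrix, config$tree_model)) |>
        (\(df) cbind(strain = rownames(df), df))(),
      file.path(out_dir, "distances.tsv")
    )
  }

  if (on("pfge")) {
    genomes <- res$cohort$genomes %||%
      (res$cohort$isolates |>
         left_join(res$population$genomes,
                   by = c(lineage_id = "strain_id")) |>
         select("isolate_id", "genome", "circular"))
    res$profiles <- t_run("pfge", {
      digests <- digest_all(genomes, config$enzyme)
      lapply(digests$profile, band_profile,
             min_size = config$min_size, max_size = config$max_size,
             comigration_tol = config$comigration_tol)
    })
    by_subject <- split(res$profiles, res$cohort$isolates$subject_id)
    res$genotypes <- bind_rows(lapply(names(by_subject), function(sid) {
      ga <- assign_genotypes(by_subject[[sid]],
                             identity_threshold = config$genotype_threshold,
                             match_tol = config$match_tol)
      ga$assignment |> mutate(subject_id = sid)
    }))
    readr_write_tsv(res$genotypes, file.path(out_dir, "genotypes.tsv"))
    write_virtual_gel(res$profiles, file.path(out_dir, "virtual_gel.txt"))
  }

  if (on("stats")) {
    res$stats_input <- t_run("stats", {
      if (!is.null(res$genotypes)) {
        res$genotypes |>
          group_by(.data$subject_id) |>
          summarise(n_genotypes = dplyr::n_distinct(.data$genotype),
                    .groups = "drop") |>
          left_join(res$cohort$subjects |> select("subject_id", "group"),
                    by = "subject_id")
      } else {
        load_cohort()
      }
    })
    res$comparisons <- all_group_comparisons(res$stats_input,
                                             mode = config$stats_mode)
    readr_write_tsv(res$comparisons, file.path(out_dir, "group_comparisons.tsv"))
    readr_write_tsv(genotype_distribution(res$stats_input),
                    file.path(out_dir, "genotype_distribution.tsv"))
  }

  manifest <- file.path(out_dir, "MANIFEST.txt")
  files <- sort(setdiff(
    dir(out_dir, recursive = TRUE),
    "MANIFEST.txt"
  ))
  params <- c(
    sprintf("stage.%s = enabled", config$stages),
    sprintf("seed = %d", config$sim$seed),
    sprintf("min_identity = %g", config$min_identity),
    sprintf("min_coverage = %g", config$min_coverage),
    sprintf("boundary_threshold = %g", config$boundary_threshold),
    sprintf("bootstrap = %d", config$bootstrap),
    sprintf("enzyme = %s", config$enzyme),
    sprintf("comigration_tol = %g", config$comigration_tol),
    sprintf("match_tol = %g", config$match_tol)
  )
  md5 <- tools::md5sum(file.path(out_dir, files))
  writeLines(c(
    "[run]",
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("package_version = %s",
            as.character(utils::packageVersion("colidiv"))),
    "[parameters]", params,
    "[files]",
    sprintf("%s = %s", files, unname(md5))
  ), manifest)
  res$manifest <- manifest
  invisible(res)
}
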