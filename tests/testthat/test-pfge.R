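mk_bp <- function(bands, id = "x", enzyme = "XbaI") {
  structure(list(isolate_id = id, enzyme = enzyme, bands = sort(bands)),
            class = "band_profile")
}

test_that("digest fragment arithmetic matches topology", {
  # circular, 100 bp, sites placed so the cuts fall at 10 and 60
  g <- paste(rep("A", 100), collapse = "")
  enz <- list(name = "toy", motif = "CCCC", cut_offset = 2L)
  substr(g, 9, 12) <- "CCCC"    # cut at 0-based 10
  substr(g, 59, 62) <- "CCCC"   # cut at 0-based 60
  d <- digest(g, circular = TRUE, enzyme = enz)
  expect_equal(d$fragment_sizes, c(50L, 50L))
  expect_equal(sum(d$fragment_sizes), 100L)

  lin <- digest(paste(rep("A", 500), collapse = ""), circular = FALSE,
                enzyme = "XbaI")
  expect_equal(lin$fragment_sizes, 500L)
  expect_equal(length(lin$sites), 0L)

  circ0 <- digest(paste(rep("A", 500), collapse = ""), circular = TRUE,
                  enzyme = "XbaI")
  expect_true(circ0$uncut)
  expect_equal(circ0$fragment_sizes, 500L)
})

test_that("motif scanning is IUPAC-aware, double-stranded and origin-aware", {
  # non-palindromic motif on the reverse strand only
  enz <- list(name = "asym", motif = "GGGATC", cut_offset = 1L)
  g <- paste0(strrep("A", 50), "GATCCC", strrep("A", 44))  # revcomp(GGGATC)
  d <- digest(g, circular = FALSE, enzyme = enz)
  expect_equal(length(d$sites), 1L)

  # IUPAC ambiguity: GGNNCC matches GGATCC
  enz2 <- list(name = "ambig", motif = "GGNNCC", cut_offset = 3L)
  g2 <- paste0(strrep("A", 30), "GGATCC", strrep("T", 30))
  expect_equal(length(digest(g2, FALSE, enz2)$sites), 1L)

  # origin-spanning site on a circular molecule
  gc <- paste0("TAGA", strrep("C", 92), "TC")  # TCTAGA across the origin
  dc <- digest(gc, circular = TRUE, enzyme = "XbaI")
  expect_equal(length(dc$sites), 1L)
  dl <- digest(gc, circular = FALSE, enzyme = "XbaI")
  expect_equal(length(dl$sites), 0L)
})

test_that("simulated genomes give one I-CeuI fragment per rRNA operon and conserve length", {
  pop <- small_population(n_lineages = 2, core_size = 5, gain_rate = 2,
                          seed = 77, genomes = TRUE)
  for (i in seq_len(nrow(pop$genomes))) {
    d <- digest(pop$genomes$genome[i], pop$genomes$circular[i], "I-CeuI")
    expect_equal(length(d$fragment_sizes), pop$config$n_rrn_operons)
    expect_equal(sum(d$fragment_sizes), nchar(pop$genomes$genome[i]))
    dx <- digest(pop$genomes$genome[i], pop$genomes$circular[i], "XbaI")
    expect_equal(sum(dx$fragment_sizes), nchar(pop$genomes$genome[i]))
    expect_gte(length(dx$sites), 20L)
  }
})

test_that("band profiles drop unresolvable fragments and merge co-migrating ones", {
  d <- structure(list(isolate_id = "x", enzyme = "XbaI",
                      fragment_sizes = c(5000L, 50000L, 50400L, 200000L),
                      sites = integer(0), topology = "circular",
                      uncut = FALSE, genome_length = 305400L),
                 class = "digest_profile")
  bp <- band_profile(d, min_size = 10000, max_size = 1.2e6,
                     comigration_tol = 0.01)
  expect_equal(bp$bands, c(50200, 200000))  # 0.8% gap merges; 5 kb dropped
  expect_error(band_profile(d, min_size = 10, max_size = 1), "min_size")
  empty <- structure(list(isolate_id = "e", enzyme = "XbaI",
                          fragment_sizes = integer(0), sites = integer(0),
                          topology = "linear", uncut = FALSE,
                          genome_length = 0L),
                     class = "digest_profile")
  expect_length(band_profile(empty)$bands, 0L)
})

test_that("Dice similarity follows band matching arithmetic", {
  a <- mk_bp(c(20000, 50000, 100000))
  expect_equal(pattern_similarity(a, a), 1)
  b <- mk_bp(c(30000, 70000, 150000, 400000))
  expect_equal(pattern_similarity(a, b), 0)
  c3 <- mk_bp(c(20000, 50000, 100000))
  c4 <- mk_bp(c(20000, 50000, 220000, 400000))
  expect_equal(pattern_similarity(c3, c4), 2 * 2 / 7)
  expect_equal(pattern_similarity(c3, c4), pattern_similarity(c4, c3))
  expect_error(pattern_similarity(a, mk_bp(1000, enzyme = "SpeI")),
               "enzyme mismatch")
})

test_that("genotype assignment clusters indistinguishable patterns", {
  same <- lapply(1:12, function(i) mk_bp(c(20000, 50000, 90000),
                                         id = sprintf("i%02d", i)))
  ga <- assign_genotypes(same)
  expect_equal(ga$n_genotypes, 1L)
  expect_true(all(ga$assignment$genotype == "G1"))

  mixed <- c(same[1:2],
             list(mk_bp(c(30000, 61000), id = "other1"),
                  mk_bp(c(30200, 61300), id = "other2")))
  ga2 <- assign_genotypes(mixed)
  expect_equal(ga2$n_genotypes, 2L)
  expect_equal(ga2$assignment$genotype, c("G1", "G1", "G2", "G2"))

  # threshold 0 collapses everything
  expect_equal(assign_genotypes(mixed, identity_threshold = 0)$n_genotypes, 1L)
  expect_error(assign_genotypes(c(same[1], list(mk_bp(1000, enzyme = "SpeI")))),
               "mix enzymes")
})

test_that("mixture lanes show the union of member bands", {
  a <- mk_bp(c(20000, 50000, 100000), id = "a")
  b <- mk_bp(c(30000, 70000, 150000, 400000), id = "b")
  mix <- mixture_lane(list(a, b))
  expect_length(mix$bands, 7L)
  expect_equal(mixture_lane(list(a))$bands, a$bands)
  expect_error(mixture_lane(list()), ">= 1 profile")
  # a member is fully contained in the mixture
  expect_equal(match_end_culture(mix, list(a, b))$status, "ambiguous")
})

test_that("end-culture matching mirrors the competition readout", {
  a <- mk_bp(c(20000, 50000, 100000), id = "a")
  b <- mk_bp(c(30000, 70000, 150000, 400000), id = "b")
  c_ <- mk_bp(c(25000, 80000, 300000), id = "c")
  res <- match_end_culture(a, list(a, b, c_))
  expect_equal(res$status, "unique")
  expect_equal(res$winner, "a")
  none <- match_end_culture(mk_bp(c(11000, 12500)), list(a, b, c_))
  expect_equal(none$status, "none")
  expect_true(is.na(none$winner))
})

test_that("three-strain competition recovers the surviving lineage from genomes", {
  pop <- small_population(n_lineages = 3, core_size = 5, gain_rate = 3,
                          seed = 99, genomes = TRUE)
  profs <- lapply(seq_len(3), function(i) {
    band_profile(digest(pop$genomes$genome[i], TRUE, "XbaI",
                        isolate_id = pop$genomes$strain_id[i]),
                 min_size = 1000)
  })
  # day-0 lane: all three patterns; end lane: the survivor only
  day0 <- mixture_lane(profs)
  expect_equal(match_end_culture(day0, profs)$status, "ambiguous")
  for (winner in 1:3) {
    res <- match_end_culture(profs[[winner]], profs)
    expect_equal(res$status, "unique")
    expect_equal(res$winner, pop$genomes$strain_id[winner])
  }
})

test_that("PFGE genotyping recovers truth genotype counts across subjects", {
  pop <- small_population(n_lineages = 5, core_size = 5, gain_rate = 3,
                          divergence_between = 0.03, seed = 13, genomes = TRUE)
  cfg <- sim_config(
    n_lineages = 5, core_size = 5, accessory_pool_size = 50, gain_rate = 3,
    gene_length_range = c(300L, 600L), divergence_between = 0.03,
    genome_length = 60000L,
    n_subjects_per_group = c(H = 6L),
    genotypes_per_subject_distribution = list(
      H = c("1" = 0.3, "2" = 0.4, "3" = 0.3)
    ),
    colonies_per_subject = 8L, seed = 14
  )
  cohort <- sample_cohort(pop, cfg)
  genomes <- dplyr::left_join(cohort$isolates,
                              pop$genomes,
                              by = c(lineage_id = "strain_id"))
  recovered <- vapply(split(seq_len(nrow(genomes)), genomes$subject_id),
                      function(idx) {
    profs <- lapply(idx, function(i) {
      band_profile(digest(genomes$genome[i], genomes$circular[i], "XbaI"),
                   min_size = 1000)
    })
    for (k in seq_along(idx)) profs[[k]]$isolate_id <- genomes$isolate_id[idx[k]]
    assign_genotypes(profs)$n_genotypes
  }, numeric(1))
  truth <- setNames(cohort$subjects$n_genotypes_true, cohort$subjects$subject_id)
  expect_equal(recovered[names(truth)], truth)
})
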