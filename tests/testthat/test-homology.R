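test_that("align_pair handles identity, substitution and prefix-coverage cases", {
  s <- paste(rep("ACGT", 75), collapse = "")
  hit <- align_pair(list(gene_id = "a", sequence = s),
                    list(gene_id = "b", sequence = s))
  expect_equal(hit$identity, 1)
  expect_equal(hit$coverage_a, 1)
  expect_equal(hit$coverage_b, 1)
  expect_true(hit$is_homolog)

  # hand alignment: 8/10 matches, full coverage, no gaps
  hit <- align_pair(list(gene_id = "a", sequence = "ACGTACGTAC"),
                    list(gene_id = "b", sequence = "ACGTACGTTT"))
  expect_equal(hit$identity, 0.8)
  expect_equal(hit$coverage_a, 1)
  expect_equal(hit$coverage_b, 1)
  expect_true(hit$is_homolog)

  # exact 700-bp prefix of a 1000-bp gene: coverage exactly 0.700 fails the
  # strict criterion
  set.seed(1)
  long <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  hit <- align_pair(list(gene_id = "long", sequence = long),
                    list(gene_id = "pre", sequence = substr(long, 1, 700)))
  expect_equal(hit$identity, 1)
  expect_equal(hit$coverage_a, 0.700)
  expect_false(hit$is_homolog)
})

test_that("non-ACGT sequences are rejected with the offending gene named", {
  expect_error(
    align_pair(list(gene_id = "okay", sequence = "ACGT"),
               list(gene_id = "dirty", sequence = "ACNT")),
    "dirty"
  )
})

test_that("unrelated random genes produce no homolog calls, with or without prefilter", {
  genes <- dplyr::bind_rows(random_gene_table(10, strain = "S1", seed = 101),
                            random_gene_table(10, strain = "S2"))
  pre <- all_vs_all(genes, prefilter = TRUE)
  full <- all_vs_all(genes, prefilter = FALSE)
  expect_equal(sum(pre$is_homolog), 0L)
  expect_equal(sum(full$is_homolog), 0L)
})

test_that("a duplicated strain hits every gene at identity 1", {
  g1 <- random_gene_table(8, strain = "S1", seed = 77)
  g2 <- g1 |> dplyr::mutate(strain_id = "S2",
                            gene_id = sub("S1", "S2", gene_id))
  hits <- all_vs_all(dplyr::bind_rows(g1, g2)) |>
    dplyr::filter(is_homolog)
  expect_equal(nrow(hits), 8L)
  expect_true(all(hits$identity == 1))
})

test_that("prefiltered search equals exhaustive alignment on mixed instances", {
  pop <- small_population(n_lineages = 3, core_size = 8,
                          divergence_between = 0.05, gain_rate = 4, seed = 88)
  genes <- pop$genes
  expect_lte(nrow(genes), 50L)
  pre <- all_vs_all(genes, prefilter = TRUE) |>
    dplyr::filter(is_homolog) |>
    dplyr::select(gene_a, gene_b, identity) |>
    dplyr::arrange(gene_a, gene_b)
  full <- all_vs_all(genes, prefilter = FALSE) |>
    dplyr::filter(is_homolog) |>
    dplyr::select(gene_a, gene_b, identity) |>
    dplyr::arrange(gene_a, gene_b)
  expect_equal(pre, full)
})

test_that("families are single-linkage components with stable ids", {
  genes <- tibble::tibble(
    gene_id = c("A", "B", "C", "D", "E"),
    strain_id = c("s1", "s2", "s3", "s4", "s5"),
    sequence = rep("ACGTACGT", 5)
  )
  hits <- tibble::tibble(
    gene_a = c("A", "B"), gene_b = c("B", "C"),
    is_homolog = TRUE
  )
  fam <- build_families(hits, genes)
  expect_equal(dplyr::n_distinct(fam$family_id), 3L)
  abc <- fam$family_id[match(c("A", "B", "C"), fam$gene_id)]
  expect_true(all(abc == "A"))  # transitive closure despite no A-C hit
  expect_equal(fam$family_id[fam$gene_id == "D"], "D")
  expect_error(
    build_families(tibble::tibble(gene_a = "A", gene_b = "Z",
                                  is_homolog = TRUE), genes),
    "unknown gene 'Z'"
  )
})

test_that("no hits yield singleton families; shared genes one family", {
  genes <- random_gene_table(5, strain = "X", seed = 5)
  fam <- build_families(
    tibble::tibble(gene_a = character(0), gene_b = character(0),
                   is_homolog = logical(0)),
    genes
  )
  expect_equal(dplyr::n_distinct(fam$family_id), 5L)

  shared <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    strain_id = c("s1", "s2", "s3"),
    sequence = rep(paste(rep("ACGT", 100), collapse = ""), 3)
  )
  fam <- build_families(all_vs_all(shared), shared)
  expect_equal(dplyr::n_distinct(fam$family_id), 1L)
  fs <- family_summary(fam)
  expect_equal(fs$n_strains, 3L)
  expect_true(fs$is_single_copy)
})

test_that("core genome is the family intersection over strains", {
  # name-equality homology: gene sets {a,b,c}, {b,c,d}, {c,d,e}
  fam <- tibble::tibble(
    family_id = c("a", "b", "c", "b", "c", "d", "c", "d", "e"),
    gene_id = paste0("g", 1:9),
    strain_id = rep(c("s1", "s2", "s3"), each = 3)
  )
  core <- core_genome(fam)
  expect_setequal(unique(core$family_id), "c")
  expect_error(core_genome(fam, character(0)), "empty strain list")
  one <- core_genome(fam, strains = "s1")
  expect_setequal(unique(one$family_id), c("a", "b", "c"))
  # a strain sharing nothing empties the core without error
  fam2 <- dplyr::bind_rows(fam, tibble::tibble(
    family_id = "z", gene_id = "g10", strain_id = "s4"
  ))
  expect_equal(nrow(core_genome(fam2)), 0L)
})

test_that("pan/core accumulation matches hand enumeration and is monotone", {
  fam <- tibble::tibble(
    family_id = c("a", "b", "c", "b", "c", "d", "c", "d", "e"),
    gene_id = paste0("g", 1:9),
    strain_id = rep(c("s1", "s2", "s3"), each = 3)
  )
  cv <- pan_genome_curve(fam, order = c("s1", "s2", "s3"))
  expect_equal(cv$data$core, c(3, 2, 1))
  expect_equal(cv$data$pan, c(3, 4, 5))

  # adding a copy of an existing strain leaves the pan unchanged at its step
  fam3 <- dplyr::bind_rows(fam, tibble::tibble(
    family_id = c("c", "d", "e"), gene_id = paste0("h", 1:3),
    strain_id = "s3bis"
  ))
  cv3 <- pan_genome_curve(fam3, order = c("s1", "s2", "s3", "s3bis"))
  expect_equal(cv3$data$pan[4], cv3$data$pan[3])

  # monotonicity under arbitrary permuted orders
  set.seed(1)
  for (i in 1:10) {
    ord <- sample(c("s1", "s2", "s3", "s3bis"))
    cvp <- pan_genome_curve(fam3, order = ord)
    expect_true(all(diff(cvp$data$core) <= 0))
    expect_true(all(diff(cvp$data$pan) >= 0))
    # sandwich: core <= min per-strain family count <= pan at every step
    expect_true(all(cvp$data$core <= 3) && all(cvp$data$pan >= 3))
  }
  expect_error(pan_genome_curve(fam, permutations = -1), "permutations")
})

test_that("family partition covers each gene exactly once", {
  pop <- small_population(seed = 60)
  fam <- build_families(all_vs_all(pop$genes), pop$genes)
  expect_setequal(fam$gene_id, pop$genes$gene_id)
  expect_equal(anyDuplicated(fam$gene_id), 0L)
  expect_equal(sum(family_summary(fam)$n_genes), nrow(pop$genes))
})

test_that("openness fit recovers a known Heaps exponent and flags closed curves", {
  k <- 1:10
  mk_curve <- function(pan) {
    structure(list(
      data = tibble::tibble(step = k, core = rep(50, 10), pan = pan),
      strains = paste0("s", k), permuted = TRUE, n_permutations = 10L
    ), class = "pan_core_curve")
  }
  fit <- openness_index(mk_curve(100 * k^0.6))
  expect_equal(fit$gamma, 0.6, tolerance = 0.05)
  expect_equal(fit$classification, "open")

  flat <- openness_index(mk_curve(rep(100, 10)))
  expect_equal(flat$classification, "closed")
  expect_true(is.na(flat$gamma))
  expect_equal(flat$new_gene_rate, 0)
  expect_equal(glance(flat)$classification, "closed")
})

test_that("gene gain drives the pan genome open; zero gain keeps it closed", {
  open_pop <- simulate_lineages(
    sim_config(n_lineages = 6, core_size = 15, accessory_pool_size = 300,
               gain_rate = 12, gene_length_range = c(300L, 500L),
               divergence_between = 0.03, genome_length = 80000L, seed = 71),
    genomes = FALSE
  )
  closed_pop <- simulate_lineages(
    sim_config(n_lineages = 6, core_size = 15, accessory_pool_size = 0,
               gain_rate = 0, gene_length_range = c(300L, 500L),
               divergence_between = 0.03, genome_length = 80000L, seed = 72),
    genomes = FALSE
  )
  curves <- lapply(list(open_pop, closed_pop), function(pop) {
    fam <- build_families(all_vs_all(pop$genes), pop$genes)
    pan_genome_curve(fam, permutations = 20, seed = 1)
  })
  ratio_final <- vapply(curves, function(cv) {
    with(cv$data, pan[length(pan)] / core[length(core)])
  }, numeric(1))
  expect_gt(ratio_final[1], ratio_final[2])
  expect_equal(openness_index(curves[[1]])$classification, "open")
  expect_equal(openness_index(curves[[2]])$classification, "closed")
})
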