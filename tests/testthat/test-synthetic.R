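test_that("drift model hits its closed-form moments and degenerate limits", {
  # mean over loci of p matches E[p0] (law of total expectation)
  cfg <- scenario_config(n_loci = 100000, n_populations = 2,
                         f_per_population = c(0.2, 0.2),
                         ancestral_freq_dist = list(dist = "beta",
                                                    shape1 = 2, shape2 = 3),
                         discovery_panel = list(pop1 = 2), seed = 10)
  freq <- simulate_frequencies(cfg)
  mc_se <- sd(freq[1, ]) / sqrt(ncol(freq))
  expect_lt(abs(mean(freq[1, ]) - 2 / 5), 4 * mc_se)
  expect_equal(dim(freq), c(2L, 100000L))
  expect_true(all(freq >= 0 & freq <= 1))

  # F -> 0 limit returns the ancestral frequencies exactly
  p0 <- c(0.1, 0.5, 0.9)
  expect_identical(ascbias:::bn_step(p0, 0), p0)
  # F = 1 rejected at configuration time
  expect_error(scenario_config(n_populations = 1, f_per_population = 1,
                               discovery_panel = list()),
               "rejected")
})

test_that("E[2p(1-p)] = 2 p0 (1-p0)(1-F) across (p0, F) settings", {
  for (case in list(c(0.3, 0.1), c(0.5, 0.05), c(0.2, 0.3))) {
    cfg <- scenario_config(
      n_loci = 60000, n_populations = 1, f_per_population = case[2],
      ancestral_freq_dist = list(dist = "fixed", value = case[1]),
      discovery_panel = list(pop1 = 2), seed = 55
    )
    p <- simulate_frequencies(cfg)[1, ]
    he <- 2 * p * (1 - p)
    expected <- 2 * case[1] * (1 - case[1]) * (1 - case[2])
    expect_lt(abs(mean(he) - expected), 4 * sd(he) / sqrt(length(he)))
  }
})

test_that("estimated F_ST increases with the generating drift parameter", {
  fst_at <- function(f) {
    cfg <- scenario_config(n_loci = 100000, n_populations = 2,
                           f_per_population = c(f, f),
                           ancestral_freq_dist = list(dist = "uniform",
                                                      min = 0.05, max = 0.95),
                           discovery_panel = list(pop1 = 2), seed = 12)
    freq <- simulate_frequencies(cfg)
    fm <- frequency_matrix(
      tibble::tibble(population = rownames(freq), n = 10),
      freq, loci = colnames(freq)
    )
    pairwise_fst(fm, "pop1", "pop2", mode = "weighted")
  }
  vals <- vapply(c(0.01, 0.05, 0.1, 0.2), fst_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("genotypes respect fixed frequencies and LD-block contrasts", {
  # p = 1 -> all dosages 2
  cfg1 <- scenario_config(n_loci = 50, n_populations = 1,
                          f_per_population = 0.2,
                          ancestral_freq_dist = list(dist = "fixed", value = 1),
                          discovery_panel = list(pop1 = 2),
                          missing_rate = 0, seed = 1)
  freq1 <- simulate_frequencies(cfg1)
  gen1 <- simulate_genotypes(freq1, cfg1)
  expect_true(all(gen1$genotypes$dosage == 2L))

  # ld_decay = 0: adjacent loci in a block uncorrelated
  cfg0 <- scenario_config(n_loci = 4000, n_populations = 1,
                          f_per_population = 0.1,
                          ancestral_freq_dist = list(dist = "uniform",
                                                     min = 0.3, max = 0.7),
                          discovery_panel = list(pop1 = 2),
                          n_individuals_per_pop = 50,
                          ld_block_size = 20, ld_decay = 0,
                          missing_rate = 0, n_chromosomes = 1, seed = 2)
  gen0 <- simulate_genotypes(simulate_frequencies(cfg0), cfg0)
  d0 <- gen0$genotypes$dosage
  adj_r <- vapply(seq_len(ncol(d0) - 1), function(j) {
    suppressWarnings(cor(d0[, j], d0[, j + 1]))
  }, numeric(1))
  adj_r <- adj_r[is.finite(adj_r)]
  expect_lt(abs(mean(adj_r)), 3 * sd(adj_r) / sqrt(length(adj_r)))

  # ld_decay = 0.95: within-block r2 exceeds between-block r2
  cfg9 <- scenario_config(n_loci = 2000, n_populations = 1,
                          f_per_population = 0.1,
                          ancestral_freq_dist = list(dist = "uniform",
                                                     min = 0.3, max = 0.7),
                          discovery_panel = list(pop1 = 2),
                          n_individuals_per_pop = 50,
                          ld_block_size = 20, ld_decay = 0.95,
                          n_templates = 2,
                          missing_rate = 0, n_chromosomes = 1, seed = 3)
  gen9 <- simulate_genotypes(simulate_frequencies(cfg9), cfg9)
  d9 <- gen9$genotypes$dosage
  blocks <- gen9$blocks
  within <- vapply(seq_len(ncol(d9) - 1), function(j) {
    if (blocks[j] != blocks[j + 1]) return(NA_real_)
    suppressWarnings(cor(d9[, j], d9[, j + 1])^2)
  }, numeric(1))
  between <- vapply(which(diff(blocks) != 0), function(j) {
    suppressWarnings(cor(d9[, j], d9[, j + 1])^2)
  }, numeric(1))
  expect_gt(mean(within, na.rm = TRUE), mean(between, na.rm = TRUE) + 0.1)
})

test_that("pooled read simulation matches its Poisson/Binomial contract", {
  cfg <- scenario_config(n_loci = 5000, n_populations = 2,
                         f_per_population = c(0.1, 0.1),
                         discovery_panel = list(pop1 = 2),
                         pool_coverage_mean = 20, seed = 5)
  sf <- withr::with_seed(5, matrix(runif(10000), 2, 5000,
                                   dimnames = list(c("pop1", "pop2"), NULL)))
  pool <- simulate_pool_reads(sf, cfg)
  md <- mean(pool$depth)
  expect_lt(abs(md - 20), 4 * sqrt(20 / length(pool$depth)))
  # frequency 0 -> no alternative reads ever
  sf0 <- matrix(0, 2, 100, dimnames = list(c("pop1", "pop2"), NULL))
  cfg0 <- scenario_config(n_loci = 100, n_populations = 2,
                          f_per_population = c(0.1, 0.1),
                          discovery_panel = list(pop1 = 2), seed = 6)
  expect_true(all(simulate_pool_reads(sf0, cfg0)$alt_reads == 0L))
})

test_that("ascertainment keeps panel-polymorphic loci and depletes rare ones", {
  cfg <- scenario_config(n_loci = 2000, n_populations = 3,
                         f_per_population = c(0.2, 0.1, 0.05),
                         discovery_panel = list(pop1 = 4, pop2 = 4),
                         seed = 30)
  sim <- simulate_scenario(cfg)
  # locus monomorphic in the panel sample is excluded
  rows <- sim$genotypes$samples$sample_id %in% sim$panel$sample_id
  dos <- sim$genotypes$dosage[rows, , drop = FALSE]
  n_obs <- colSums(!is.na(dos))
  p <- colSums(dos, na.rm = TRUE) / (2 * n_obs)
  mono <- !is.na(p) & (p == 0 | p == 1)
  expect_true(all(!sim$truth$ascertained[mono]))

  # maf 0 + panel = everyone -> retained set = all polymorphic loci
  cfg_all <- scenario_config(n_loci = 500, n_populations = 2,
                             f_per_population = c(0.1, 0.1),
                             n_individuals_per_pop = 6,
                             discovery_panel = list(pop1 = 6, pop2 = 6),
                             ascertainment_maf_min = 0, missing_rate = 0,
                             seed = 31)
  sim_all <- simulate_scenario(cfg_all)
  p_all <- colSums(sim_all$genotypes$dosage) /
    (2 * nrow(sim_all$genotypes$dosage))
  expect_identical(sim_all$truth$ascertained,
                   unname(p_all > 0 & p_all < 1))

  # panel larger than the population is rejected
  expect_error(
    simulate_scenario(scenario_config(n_loci = 50, n_populations = 2,
                                      f_per_population = c(0.1, 0.1),
                                      n_individuals_per_pop = 3,
                                      discovery_panel = list(pop1 = 5),
                                      seed = 32)),
    "panel"
  )
})

test_that("two-clade drift structure is recovered by NJ on true frequencies", {
  cfg <- scenario_config(
    population_tree = "((a:0.05,b:0.05):0.25,(c:0.05,d:0.05):0.25);",
    n_loci = 20000, n_individuals_per_pop = 10,
    discovery_panel = list(a = 2), seed = 44
  )
  freq <- simulate_frequencies(cfg)
  fm <- frequency_matrix(
    tibble::tibble(population = rownames(freq), n = 10),
    freq, loci = colnames(freq)
  )
  est <- neighbor_joining(nei_distance_matrix(fm))
  generating <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  expect_equal(partition_distance(est, generating), 0)
})

test_that("simulation output is bit-reproducible at a fixed seed", {
  cfg <- scenario_config(n_loci = 300, n_populations = 3,
                         f_per_population = c(0.2, 0.1, 0.05),
                         discovery_panel = list(pop1 = 3), seed = 99)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$truth$true_freqs, s2$truth$true_freqs)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$pool$alt_reads, s2$pool$alt_reads)
  expect_identical(s1$truth$ascertained, s2$truth$ascertained)
})

test_that("packaged scenarios load with their documented shapes", {
  cfg_d <- load_scenario("default_bias")
  expect_equal(cfg_d$n_loci, 50000L)
  expect_equal(length(cfg_d$populations), 8L)
  expect_equal(names(cfg_d$discovery_panel), c("pop1", "pop2"))
  expect_equal(cfg_d$ascertainment_maf_min, 0.05)
  expect_equal(cfg_d$seed, 1L)
  cfg_n <- load_scenario("null")
  expect_equal(length(cfg_n$discovery_panel), 0L)
  expect_equal(cfg_n$ld_decay, 0)
  cfg_l <- load_scenario("strong_ld")
  expect_equal(cfg_l$ld_decay, 0.95)
  expect_error(load_scenario("nonexistent"), "unknown scenario")
})
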