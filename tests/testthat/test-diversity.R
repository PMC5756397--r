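test_that("sample frequencies match a brute-force per-genotype tally", {
  # 2 diploids with dosages {1, 2} -> p = 0.75
  geno <- make_geno(rbind(1L, 2L))
  expect_equal(unname(sample_frequencies(geno)$freq[1, 1]), 0.75)
  # all-reference population -> p = 0
  geno0 <- make_geno(matrix(0L, 4, 2))
  expect_equal(unname(sample_frequencies(geno0)$freq), matrix(0, 1, 2))

  geno_r <- random_geno(10, 50, pops = c("popA", "popB"), seed = 14,
                        missing_rate = 0.1)
  fm <- sample_frequencies(geno_r)
  for (pp in c("popA", "popB")) {
    rows <- geno_r$samples$population == pp
    for (j in c(1, 17, 50)) {
      d <- geno_r$dosage[rows, j]
      d <- d[!is.na(d)]
      expect_equal(unname(fm$freq[match(pp, fm$populations$population), j]),
                   sum(d) / (2 * length(d)))
    }
  }
})

test_that("pooled frequency estimator is the read proportion and is unbiased", {
  snps <- make_snps(2)
  pops <- tibble::tibble(population = "popA", n_individuals = 10L)
  pool <- pool_table(snps, pops, matrix(c(5L, 0L), 1), matrix(20L, 1, 2))
  expect_equal(unname(pooled_frequencies(pool)$freq[1, ]), c(0.25, 0))

  # Monte-Carlo unbiasedness: mean(estimate - truth) within 3 binomial SE of 0
  n_l <- 10000
  cfg <- scenario_config(n_loci = n_l, n_populations = 1,
                         f_per_population = 0.1,
                         discovery_panel = list(pop1 = 2),
                         ancestral_freq_dist = list(dist = "uniform",
                                                    min = 0.2, max = 0.8),
                         seed = 33)
  truth <- withr::with_seed(33, matrix(runif(n_l, 0.1, 0.9), 1,
                                       dimnames = list("pop1", NULL)))
  pool2 <- simulate_pool_reads(truth, cfg)
  est <- pooled_frequencies(pool2)$freq
  err <- est[1, ] - truth[1, ]
  se <- sqrt(mean(truth * (1 - truth) / 20) / n_l)
  expect_lt(abs(mean(err, na.rm = TRUE)), 3 * se)
})

test_that("AFS binning uses 40 left-closed bins with a closed last bin", {
  sp <- afs(rep(0, 10))
  expect_equal(sp$proportion[1], 1)
  expect_equal(sum(sp$proportion), 1)

  sp1 <- afs(c(1, 0.975, 0.9749))
  expect_equal(sp1$count[40], 2L)  # 1 and 0.975 share the last bin
  expect_equal(sp1$count[39], 1L)

  expect_error(afs(c(0.5, 1.2)), "0, 1")

  withr::with_seed(5, {
    u <- runif(100000)
  })
  spu <- afs(u)
  se <- sqrt(0.025 * 0.975 / 100000)
  expect_true(all(abs(spu$proportion - 0.025) < 4 * se))

  # pooling two spectra by SNP-count weights = spectrum of concatenation
  a <- withr::with_seed(6, runif(1000))
  b <- withr::with_seed(7, runif(500))
  sa <- afs(a); sb <- afs(b)
  pooled <- (sa$proportion * 1000 + sb$proportion * 500) / 1500
  expect_equal(pooled, afs(c(a, b))$proportion)
})

test_that("expected heterozygosity follows 2p(1-p) and its closed-form mean", {
  fm <- frequency_matrix(tibble::tibble(population = "p1", n = 10),
                         matrix(0.5, 1, 4), loci = paste0("L", 1:4))
  expect_equal(expected_heterozygosity(fm)$he, 0.5)
  fm0 <- frequency_matrix(tibble::tibble(population = "p1", n = 10),
                          matrix(0, 1, 4), loci = paste0("L", 1:4))
  expect_equal(expected_heterozygosity(fm0)$he, 0)
  expect_error(expected_heterozygosity(fm, subset = character()), "empty")

  # E[2p(1-p)] = 2 p0 (1-p0) (1-F) under the drift model
  for (case in list(c(0.3, 0.1, 0.378), c(0.5, 0.05, 0.475))) {
    cfg <- scenario_config(
      n_loci = 100000, n_populations = 1, f_per_population = case[2],
      ancestral_freq_dist = list(dist = "fixed", value = case[1]),
      discovery_panel = list(pop1 = 2), seed = 77
    )
    p <- simulate_frequencies(cfg)[1, ]
    he <- 2 * p * (1 - p)
    mc_se <- sd(he) / sqrt(length(he))
    expect_lt(abs(mean(he) - case[3]), 4 * mc_se)
  }
})

test_that("pairwise F_ST reproduces trivial cases and a per-locus loop oracle", {
  # fixed difference: p = (0, 1) -> F_ST = 1; identical -> 0
  fm <- frequency_matrix(
    tibble::tibble(population = c("a", "b"), n = c(10, 10)),
    rbind(c(0, 0.3), c(1, 0.3)), loci = c("L1", "L2")
  )
  expect_equal(pairwise_fst(fm, "a", "b", subset = "L1"), 1)
  expect_equal(pairwise_fst(fm, "a", "b", subset = "L2"), 0)

  withr::with_seed(19, {
    p <- matrix(runif(2000), 2, 1000)
  })
  fmr <- frequency_matrix(
    tibble::tibble(population = c("a", "b"), n = c(12, 30)),
    p, loci = paste0("L", 1:1000)
  )
  # scalar per-locus loop oracle, weighted mode
  n1 <- 12; n2 <- 30; nbar <- 21; r <- 2
  vals <- numeric(0)
  for (l in seq_len(1000)) {
    pbar <- (n1 * p[1, l] + n2 * p[2, l]) / (r * nbar)
    s2 <- (n1 * (p[1, l] - pbar)^2 + n2 * (p[2, l] - pbar)^2) / (r * nbar)
    den <- pbar * (1 - pbar)
    if (den > 0) vals <- c(vals, s2 / den)
  }
  expect_equal(pairwise_fst(fmr, "a", "b", mode = "weighted"), mean(vals),
               tolerance = 1e-12)
  # equal-size oracle
  vals_eq <- numeric(0)
  for (l in seq_len(1000)) {
    pbar <- mean(p[, l])
    s2 <- sum((p[, l] - pbar)^2) / 2
    den <- pbar * (1 - pbar)
    if (den > 0) vals_eq <- c(vals_eq, s2 / den)
  }
  expect_equal(pairwise_fst(fmr, "a", "b", mode = "equal"), mean(vals_eq),
               tolerance = 1e-12)
})

test_that("F_ST is symmetric, bounded, label-swap invariant, and the weighted
           mode equals the equal mode at equal sample sizes", {
  withr::with_seed(23, {
    p <- matrix(runif(600), 2, 300)
  })
  fm_eq <- frequency_matrix(
    tibble::tibble(population = c("a", "b"), n = c(15, 15)),
    p, loci = paste0("L", 1:300)
  )
  expect_equal(pairwise_fst(fm_eq, "a", "b", mode = "weighted"),
               pairwise_fst(fm_eq, "a", "b", mode = "equal"),
               tolerance = 1e-12)
  f_ab <- pairwise_fst(fm_eq, "a", "b")
  expect_equal(f_ab, pairwise_fst(fm_eq, "b", "a"))
  expect_gte(f_ab, 0); expect_lte(f_ab, 1)
  # swap ref/alt labels at a subset of loci: p -> 1 - p in both populations
  p2 <- p
  p2[, 1:100] <- 1 - p2[, 1:100]
  fm_swap <- frequency_matrix(
    tibble::tibble(population = c("a", "b"), n = c(15, 15)),
    p2, loci = paste0("L", 1:300)
  )
  expect_equal(pairwise_fst(fm_swap, "a", "b"), f_ab, tolerance = 1e-12)
})

test_that("Nei distance matches a naive double-loop oracle", {
  fm_id <- frequency_matrix(
    tibble::tibble(population = c("a", "b"), n = c(5, 5)),
    rbind(c(0.2, 0.7), c(0.2, 0.7)), loci = c("L1", "L2")
  )
  expect_equal(unname(nei_distance_matrix(fm_id)), matrix(0, 2, 2))

  withr::with_seed(29, {
    p <- matrix(runif(2000), 4, 500)
  })
  fm <- frequency_matrix(
    tibble::tibble(population = letters[1:4], n = rep(8, 4)),
    p, loci = paste0("L", 1:500)
  )
  d <- nei_distance_matrix(fm)
  oracle <- matrix(0, 4, 4)
  for (x in 1:4) for (y in 1:4) {
    jx <- jy <- jxy <- 0
    for (l in 1:500) {
      jx <- jx + p[x, l]^2 + (1 - p[x, l])^2
      jy <- jy + p[y, l]^2 + (1 - p[y, l])^2
      jxy <- jxy + p[x, l] * p[y, l] + (1 - p[x, l]) * (1 - p[y, l])
    }
    oracle[x, y] <- -log(jxy / sqrt(jx * jy))
  }
  diag(oracle) <- 0
  expect_equal(unname(d), oracle, tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("frequency PCA matches a covariance-eigendecomposition oracle and
           separates simulated clades on PC1", {
  cfg <- scenario_config(
    population_tree = "((a:0.02,b:0.02):0.3,(c:0.02,d:0.02):0.3);",
    n_loci = 2000, n_individuals_per_pop = 10,
    discovery_panel = list(a = 2), seed = 41
  )
  freqs <- simulate_frequencies(cfg)
  fm <- frequency_matrix(
    tibble::tibble(population = rownames(freqs), n = 10),
    freqs, loci = colnames(freqs)
  )
  res <- pca_frequencies(fm, k = 3)
  # oracle: eigendecomposition of the covariance of centered rows
  X <- scale(freqs, center = TRUE, scale = FALSE)
  ev <- eigen(tcrossprod(X) / 1, symmetric = TRUE)
  tot <- sum(diag(tcrossprod(X)))
  expect_equal(res$var_explained, (ev$values / tot)[1:3], tolerance = 1e-8)
  # PC1 coordinates match up to sign
  pc1 <- res$coordinates$PC1
  o1 <- ev$vectors[, 1] * sqrt(ev$values[1])
  expect_equal(abs(cor(pc1, o1)), 1, tolerance = 1e-8)
  # clades separate with a sign-invariant gap
  clade <- c(1, 1, 2, 2)
  expect_true(max(pc1[clade == 1]) < min(pc1[clade == 2]) ||
                max(pc1[clade == 2]) < min(pc1[clade == 1]))
  expect_true(all(diff(res$var_explained) <= 1e-12))
  expect_true(all(res$var_explained >= 0 & res$var_explained <= 1))
  # two identical populations coincide on all components
  fm2 <- frequency_matrix(
    tibble::tibble(population = c("x", "y", "z"), n = 5),
    rbind(freqs[1, ], freqs[1, ], freqs[3, ]), loci = colnames(freqs)
  )
  res2 <- pca_frequencies(fm2, k = 1)
  expect_equal(res2$coordinates$PC1[1], res2$coordinates$PC1[2],
               tolerance = 1e-8)
})

test_that("genic classification is inclusive at boundaries and matches an
           all-pairs oracle", {
  snps <- make_snps(4, chrom = "1", start_pos = 100L, step = 100L)
  genes <- data.frame(chromosome = "1", start = c(200L, 350L),
                      end = c(250L, 360L))
  res <- genic_classification(snps, genes)
  # SNP at the gene start coordinate is genic (inclusive boundary)
  expect_equal(res$classes$genic, c(FALSE, TRUE, FALSE, FALSE))

  expect_equal(genic_classification(
    snps, data.frame(chromosome = character(), start = integer(),
                     end = integer())
  )$classes$genic, rep(FALSE, 4))

  withr::with_seed(47, {
    snps_r <- make_snps(1000, chrom = sample(c("1", "2"), 1000, TRUE),
                        start_pos = 1L, step = 0L)
    snps_r$position <- sample.int(100000, 1000)
    starts <- sample.int(100000, 50)
    genes_r <- data.frame(chromosome = sample(c("1", "2"), 50, TRUE),
                          start = starts,
                          end = starts + sample.int(5000, 50))
  })
  res_r <- genic_classification(snps_r, genes_r)
  oracle <- vapply(seq_len(1000), function(i) {
    any(genes_r$chromosome == snps_r$chromosome[i] &
          genes_r$start <= snps_r$position[i] &
          genes_r$end >= snps_r$position[i])
  }, logical(1))
  expect_identical(res_r$classes$genic, oracle)
})
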