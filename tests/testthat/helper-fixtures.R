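# Small programmatic fixtures shared across test files.

make_snps <- function(n, chrom = "1", start_pos = 100L, step = 100L,
                      ref = "A", alt = "G", prefix = "s") {
  tibble::tibble(
    id = paste0(prefix, seq_len(n)),
    chromosome = rep_len(chrom, n),
    position = as.integer(start_pos + step * (seq_len(n) - 1L)),
    ref_allele = rep_len(ref, n),
    alt_allele = rep_len(alt, n)
  )
}

make_geno <- function(dosage, populations = NULL, snps = NULL) {
  dosage <- as.matrix(dosage)
  n_s <- nrow(dosage); n_l <- ncol(dosage)
  if (is.null(snps)) snps <- make_snps(n_l)
  if (is.null(populations)) populations <- rep("popA", n_s)
  samples <- tibble::tibble(
    sample_id = paste0("ind", seq_len(n_s)),
    population = populations
  )
  genotype_matrix(snps, samples, dosage)
}

# Random genotype matrix with per-population HWE frequencies.
random_geno <- function(n_per_pop, n_loci, pops = c("popA", "popB"),
                        seed = 1, missing_rate = 0) {
  withr::with_seed(seed, {
    dos <- do.call(rbind, lapply(seq_along(pops), function(i) {
      p <- runif(n_loci, 0.05, 0.95)
      matrix(rbinom(n_per_pop * n_loci, 2, rep(p, each = n_per_pop)),
             n_per_pop, n_loci)
    }))
    if (missing_rate > 0) {
      dos[matrix(runif(length(dos)) < missing_rate, nrow(dos))] <- NA_integer_
    }
    make_geno(dos, populations = rep(pops, each = n_per_pop))
  })
}

# Pool table whose read counts reproduce the given frequencies exactly
# (depth = 2 * n per locus, alt = allele count), so pooled_frequencies()
# returns the sample frequencies with no read noise.
exact_pool_from_geno <- function(geno) {
  fm <- sample_frequencies(geno)
  n2 <- 2L * fm$populations$n
  depth <- matrix(rep(n2, times = length(fm$loci)),
                  nrow = nrow(fm$freq))
  alt <- round(fm$freq * depth)
  pool_table(geno$snps,
             tibble::tibble(population = fm$populations$population,
                            n_individuals = fm$populations$n),
             alt, depth)
}

write_test_vcf <- function(path, chrom, pos, ref, alt, gt_matrix,
                           sample_ids = paste0("ind", seq_len(nrow(gt_matrix)))) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  for (j in seq_len(ncol(gt_matrix))) {
    lines <- c(lines, paste(c(
      chrom[j], pos[j], paste0("v", j), ref[j], alt[j], ".", "PASS", ".",
      "GT", gt_matrix[, j]
    ), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

random_binary_tree <- function(n_tips, seed, min_len = 0.05, max_len = 1) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_tips, rooted = FALSE,
                     tip.label = paste0("t", seq_len(n_tips)))
    tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
    tr
  })
}

# Heavy simulations reused across test files, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_scenario <- function() {
  cached("default_scenario", function() simulate_scenario("default_bias"))
}

strong_ld_scenario <- function() {
  cached("strong_ld_scenario", function() simulate_scenario("strong_ld"))
}
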