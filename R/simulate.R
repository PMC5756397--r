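#' Scenario configuration for the synthetic-data generator
#'
#' Describes the simulated study: structured populations drifting from a
#' common ancestor under the Balding–Nichols model, HWE diploid genotypes
#' with template-copy LD blocks, pooled binomial read sampling, and SNP
#' discovery in a small panel with a MAF cutoff — the statistical structure
#' an array/whole-genome comparison assumes.
#'
#' @param n_populations Number of populations (ignored when
#'   `population_tree` is given; then the tips define the populations).
#' @param population_tree Optional Newick string or `phylo`; edge lengths are
#'   per-edge drift parameters F in (0, 1) applied recursively, so clade
#'   structure is recoverable.
#' @param f_per_population Drift parameter per population in (0, 1) (star
#'   topology; recycled to `n_populations`).
#' @param ancestral_freq_dist List describing the ancestral frequency
#'   distribution: `list(dist = "beta", shape1, shape2)`,
#'   `list(dist = "uniform", min, max)` or `list(dist = "fixed", value)`.
#' @param n_loci Number of simulated loci.
#' @param n_individuals_per_pop Diploid individuals per population
#'   (scalar or per-population vector).
#' @param pool_coverage_mean Poisson mean read depth per population per locus.
#' @param discovery_panel Named list/vector: populations contributing to the
#'   SNP discovery panel and how many individuals each contributes.
#' @param ascertainment_maf_min Panel MAF cutoff for a locus to be retained
#'   on the "array".
#' @param reference_populations Populations treated as the wild reference for
#'   the polymorphism filter downstream.
#' @param ld_block_size Loci per LD block.
#' @param ld_decay Copy fidelity in \[0, 1\]: probability that a haplotype
#'   copies the block template at a locus rather than drawing fresh; 0 gives
#'   independent loci.
#' @param n_templates Template haplotypes per block per population; fewer
#'   templates give stronger within-block LD.
#' @param missing_rate Per-genotype missing probability (array artifact).
#' @param n_chromosomes Loci are split evenly over this many chromosomes,
#'   named "1", "2", ...
#' @param seed Root seed; all stages derive named substreams from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_populations = 8,
                            population_tree = NULL,
                            f_per_population = c(0.35, 0.40, 0.05, 0.08,
                                                 0.15, 0.22, 0.30, 0.50),
                            ancestral_freq_dist = list(dist = "beta",
                                                       shape1 = 0.5,
                                                       shape2 = 2),
                            n_loci = 50000,
                            n_individuals_per_pop = 10,
                            pool_coverage_mean = 20,
                            discovery_panel = list(pop1 = 4, pop2 = 4),
                            ascertainment_maf_min = 0.05,
                            reference_populations = c("pop3", "pop4"),
                            ld_block_size = 20,
                            ld_decay = 0.5,
                            n_templates = 4,
                            missing_rate = 0.002,
                            n_chromosomes = 5,
                            seed = 1) {
  if (!is.null(population_tree)) {
    tree <- if (inherits(population_tree, "phylo")) population_tree
      else ape::read.tree(text = population_tree)
    pops <- tree$tip.label
    n_populations <- length(pops)
  } else {
    tree <- NULL
    pops <- paste0("pop", seq_len(n_populations))
    f_per_population <- rep_len(f_per_population, n_populations)
    if (any(f_per_population <= 0 | f_per_population >= 1)) {
      abort("drift parameters must lie strictly in (0, 1); F = 1 is rejected")
    }
  }
  stopifnot(
    n_loci >= 1,
    ascertainment_maf_min >= 0, ascertainment_maf_min <= 1,
    ld_decay >= 0, ld_decay <= 1,
    missing_rate >= 0, missing_rate <= 1,
    ld_block_size >= 1, n_templates >= 1, pool_coverage_mean > 0
  )
  panel_pops <- names(discovery_panel)
  if (length(discovery_panel) && !all(panel_pops %in% pops)) {
    abort("discovery panel populations must be among the scenario populations")
  }
  structure(list(
    populations = pops,
    population_tree = tree,
    f_per_population = if (is.null(tree)) {
      setNames(f_per_population, pops)
    } else NULL,
    ancestral_freq_dist = ancestral_freq_dist,
    n_loci = as.integer(n_loci),
    n_individuals_per_pop = setNames(
      rep_len(as.integer(n_individuals_per_pop), length(pops)), pops),
    pool_coverage_mean = pool_coverage_mean,
    discovery_panel = discovery_panel,
    ascertainment_maf_min = ascertainment_maf_min,
    reference_populations = reference_populations,
    ld_block_size = as.integer(ld_block_size),
    ld_decay = ld_decay,
    n_templates = as.integer(n_templates),
    missing_rate = missing_rate,
    n_chromosomes = as.integer(n_chromosomes),
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Load a packaged or on-disk scenario
#'
#' Three scenarios ship with the package: `"null"` (no ascertainment, no LD),
#' `"default_bias"` (discovery-panel ascertainment with a MAF cutoff) and
#' `"strong_ld"` (pronounced LD blocks for exercising pruning).
#'
#' @param name Packaged scenario name or path to a YAML file with
#'   [scenario_config()] keys.
#' @return A `scenario_config`.
#' @export
load_scenario <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "ascbias")
  }
  if (!nzchar(path) || !file.exists(path)) {
    abort(sprintf("unknown scenario: %s", name))
  }
  cfg <- yaml::read_yaml(path)
  cfg$name <- NULL
  if (!is.null(cfg$discovery_panel)) {
    cfg$discovery_panel <- as.list(cfg$discovery_panel)
  }
  do.call(scenario_config, cfg)
}

draw_ancestral <- function(n, spec) {
  switch(spec$dist,
    beta = rbeta(n, spec$shape1, spec$shape2),
    uniform = runif(n, spec$min, spec$max),
    fixed = rep(spec$value, n),
    abort(sprintf("unknown ancestral distribution: %s", spec$dist))
  )
}

# One Balding-Nichols drift step: child frequencies around parent p with
# drift F. F = 0 returns p unchanged; fixed parents stay fixed.
bn_step <- function(p, f) {
  if (f == 0) return(p)
  out <- p
  inner <- p > 0 & p < 1
  out[inner] <- rbeta(sum(inner),
                      p[inner] * (1 - f) / f,
                      (1 - p[inner]) * (1 - f) / f)
  out
}

#' Simulate true per-population allele frequencies
#'
#' Ancestral frequencies are drawn from the configured distribution; each
#' population's frequencies drift away under the Balding–Nichols Beta model
#' (star topology), or recursively along the edges of `population_tree` when
#' one is given.
#'
#' @param cfg A [scenario_config()].
#' @return Matrix (populations x loci) of true frequencies, with the
#'   ancestral vector in attribute `p0`.
#' @export
simulate_frequencies <- function(cfg) {
  withr::with_seed(substream_seed(cfg$seed, "frequencies"), {
    p0 <- draw_ancestral(cfg$n_loci, cfg$ancestral_freq_dist)
    if (is.null(cfg$population_tree)) {
      freq <- t(vapply(cfg$populations, function(pp) {
        bn_step(p0, cfg$f_per_population[[pp]])
      }, numeric(cfg$n_loci)))
    } else {
      tree <- cfg$population_tree
      if (any(tree$edge.length <= 0 | tree$edge.length >= 1)) {
        abort("tree edge lengths are drift parameters and must lie in (0, 1)")
      }
      n_tip <- length(tree$tip.label)
      node_freq <- vector("list", n_tip + tree$Nnode)
      root <- n_tip + 1L
      node_freq[[root]] <- p0
      pre <- ape::reorder.phylo(tree, "cladewise")
      for (e in seq_len(nrow(pre$edge))) {
        parent <- pre$edge[e, 1]; child <- pre$edge[e, 2]
        node_freq[[child]] <- bn_step(node_freq[[parent]],
                                      pre$edge.length[e])
      }
      freq <- do.call(rbind, node_freq[seq_len(n_tip)])
    }
    rownames(freq) <- cfg$populations
    colnames(freq) <- locus_ids(cfg)
    attr(freq, "p0") <- p0
    freq
  })
}

locus_ids <- function(cfg) {
  chrom <- chrom_of_locus(cfg)
  pos <- pos_of_locus(cfg)
  paste0("snp_", chrom, "_", pos)
}

chrom_of_locus <- function(cfg) {
  per <- ceiling(cfg$n_loci / cfg$n_chromosomes)
  as.character(rep(seq_len(cfg$n_chromosomes), each = per)[seq_len(cfg$n_loci)])
}

pos_of_locus <- function(cfg) {
  per <- ceiling(cfg$n_loci / cfg$n_chromosomes)
  within <- ((seq_len(cfg$n_loci) - 1L) %% per) + 1L
  within * 1000L
}

scenario_snp_table <- function(cfg) {
  tibble(
    id = locus_ids(cfg),
    chromosome = chrom_of_locus(cfg),
    position = pos_of_locus(cfg),
    ref_allele = "A",
    alt_allele = "G"
  )
}

#' Simulate diploid genotypes with LD blocks
#'
#' Dosages are Binomial(2, p) under HWE. Within LD blocks of
#' `ld_block_size` loci, each haplotype copies one of `n_templates` block
#' template haplotypes with per-locus probability `ld_decay` (and draws fresh
#' from the population frequency otherwise), producing correlated dosage
#' columns while preserving marginal frequencies. Missing genotypes are then
#' planted uniformly at `missing_rate`.
#'
#' @param true_freqs Populations x loci matrix from [simulate_frequencies()].
#' @param cfg A [scenario_config()].
#' @return List with `genotypes` (a [genotype_matrix()]), `sample_freqs`
#'   (populations x loci allele frequencies of the complete, pre-missingness
#'   genotypes) and `blocks` (block id per locus).
#' @export
simulate_genotypes <- function(true_freqs, cfg) {
  L <- ncol(true_freqs)
  block <- rep(seq_len(ceiling(L / cfg$ld_block_size)),
               each = cfg$ld_block_size)[seq_len(L)]
  # Blocks must not straddle chromosomes.
  chrom <- chrom_of_locus(cfg)
  block <- as.integer(factor(paste(chrom, block, sep = "_"),
                             levels = unique(paste(chrom, block, sep = "_"))))
  withr::with_seed(substream_seed(cfg$seed, "genotypes"), {
    pops <- rownames(true_freqs)
    dos_list <- vector("list", length(pops))
    sf <- matrix(NA_real_, length(pops), L,
                 dimnames = list(pops, colnames(true_freqs)))
    for (i in seq_along(pops)) {
      n_i <- cfg$n_individuals_per_pop[[pops[i]]]
      H <- 2L * n_i
      p <- true_freqs[i, ]
      fresh <- matrix(rbinom(H * L, 1L, rep(p, each = H)), H, L)
      if (cfg$ld_decay > 0) {
        K <- cfg$n_templates
        tmpl <- matrix(rbinom(K * L, 1L, rep(p, each = K)), K, L)
        nb <- max(block)
        choice <- matrix(sample.int(K, H * nb, replace = TRUE), H, nb)
        choice_full <- choice[, block, drop = FALSE]
        copy <- matrix(runif(H * L) < cfg$ld_decay, H, L)
        tval <- matrix(
          tmpl[cbind(as.vector(choice_full), rep(seq_len(L), each = H))],
          H, L
        )
        hap <- ifelse(copy, tval, fresh)
      } else {
        hap <- fresh
      }
      dos <- hap[seq(1, H, by = 2), , drop = FALSE] +
        hap[seq(2, H, by = 2), , drop = FALSE]
      sf[i, ] <- colSums(dos) / H
      dos_list[[i]] <- dos
    }
    dos <- do.call(rbind, dos_list)
    if (cfg$missing_rate > 0) {
      dos[matrix(runif(length(dos)) < cfg$missing_rate, nrow(dos))] <- NA_integer_
    }
    samples <- tibble(
      sample_id = paste0(rep(pops, times = cfg$n_individuals_per_pop[pops]),
                         "_ind",
                         unlist(lapply(cfg$n_individuals_per_pop[pops],
                                       seq_len))),
      population = rep(pops, times = cfg$n_individuals_per_pop[pops])
    )
    list(
      genotypes = genotype_matrix(scenario_snp_table(cfg), samples, dos),
      sample_freqs = sf,
      blocks = block
    )
  })
}

#' Simulate pooled sequencing reads
#'
#' Depth is Poisson(`pool_coverage_mean`) per population per locus;
#' alternative-read counts are Binomial(depth, sample frequency).
#'
#' @param sample_freqs Populations x loci matrix of sample allele
#'   frequencies (e.g. from [simulate_genotypes()]), or a [genotype_matrix()]
#'   from which they are computed.
#' @param cfg A [scenario_config()].
#' @return A [pool_table()].
#' @export
simulate_pool_reads <- function(sample_freqs, cfg) {
  if (inherits(sample_freqs, "geno_matrix")) {
    fm <- sample_frequencies(sample_freqs)
    sample_freqs <- fm$freq
  }
  withr::with_seed(substream_seed(cfg$seed, "pool_reads"), {
    n_pop <- nrow(sample_freqs)
    L <- ncol(sample_freqs)
    depth <- matrix(rpois(n_pop * L, cfg$pool_coverage_mean), n_pop, L)
    alt <- matrix(rbinom(n_pop * L, as.vector(depth),
                         as.vector(sample_freqs)), n_pop, L)
    pool_table(
      scenario_snp_table(cfg),
      tibble(population = rownames(sample_freqs),
             n_individuals = unname(cfg$n_individuals_per_pop[
               rownames(sample_freqs)])),
      alt, depth
    )
  })
}

#' Ascertain loci through a discovery panel
#'
#' Draws the configured panel individuals (once, seeded), computes the panel
#' MAF from their genotypes (2 x panel individuals alleles) and retains a
#' locus iff it is polymorphic in the panel sample and its panel MAF is at
#' least `ascertainment_maf_min`.
#'
#' @param geno A [genotype_matrix()] over all simulated loci.
#' @param cfg A [scenario_config()].
#' @return List with `subset` (retained SNP ids), `mask` (logical over all
#'   loci) and `panel` (tibble of panel members).
#' @export
ascertain <- function(geno, cfg) {
  if (!length(cfg$discovery_panel)) {
    abort("the scenario defines no discovery panel")
  }
  withr::with_seed(substream_seed(cfg$seed, "ascertainment"), {
    members <- purrr::imap(cfg$discovery_panel, function(n_pick, pop) {
      avail <- geno$samples$sample_id[geno$samples$population == pop]
      if (n_pick > length(avail)) {
        abort(sprintf("panel wants %d individuals from %s but only %d exist",
                      n_pick, pop, length(avail)))
      }
      sample(avail, n_pick)
    })
    panel <- tibble(
      sample_id = unlist(members, use.names = FALSE),
      population = rep(names(cfg$discovery_panel),
                       times = lengths(members))
    )
    rows <- geno$samples$sample_id %in% panel$sample_id
    dos <- geno$dosage[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(dos))
    p <- colSums(dos, na.rm = TRUE) / (2 * n_obs)
    maf <- pmin(p, 1 - p)
    mask <- !is.na(p) & p > 0 & p < 1 & maf >= cfg$ascertainment_maf_min
    list(subset = geno$snps$id[mask], mask = unname(mask), panel = panel)
  })
}

#' Simulate a full scenario
#'
#' Runs [simulate_frequencies()], [simulate_genotypes()],
#' [simulate_pool_reads()] and [ascertain()] and bundles the results: the
#' "array" side (genotypes at ascertained loci), the "reference" side (pooled
#' reads at all loci) and the generating truth.
#'
#' @param cfg A [scenario_config()], or a scenario name/path for
#'   [load_scenario()].
#' @return A `scenario_data` list with elements `config`, `truth` (true and
#'   sample frequencies, ascertainment mask, block memberships), `genotypes`
#'   (all loci), `array` (ascertained loci only), `pool`, `panel`.
#' @export
simulate_scenario <- function(cfg = scenario_config()) {
  if (is.character(cfg)) cfg <- load_scenario(cfg)
  true_freqs <- simulate_frequencies(cfg)
  gen <- simulate_genotypes(true_freqs, cfg)
  pool <- simulate_pool_reads(gen$sample_freqs, cfg)
  asc <- if (length(cfg$discovery_panel)) {
    ascertain(gen$genotypes, cfg)
  } else {
    list(subset = gen$genotypes$snps$id,
         mask = rep(TRUE, cfg$n_loci), panel = tibble())
  }
  structure(list(
    config = cfg,
    truth = list(
      true_freqs = true_freqs,
      p0 = attr(true_freqs, "p0"),
      sample_freqs = gen$sample_freqs,
      ascertained = asc$mask,
      blocks = gen$blocks
    ),
    genotypes = gen$genotypes,
    array = subset_loci(gen$genotypes, asc$subset),
    pool = pool,
    panel = asc$panel
  ), class = "scenario_data")
}

#' @export
print.scenario_data <- function(x, ...) {
  cat(sprintf(
    "<scenario_data> %d populations, %d loci (%d ascertained), seed %d\n",
    length(x$config$populations), x$config$n_loci,
    sum(x$truth$ascertained), x$config$seed
  ))
  invisible(x)
}
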