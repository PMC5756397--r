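#' Per-population allele frequencies from individual genotypes
#'
#' For each population and locus, the alternative-allele frequency is the alt
#' allele count divided by twice the number of non-missing diploid genotypes.
#' A locus with no genotyped individuals in a population gets `NA` there.
#'
#' @param geno A [genotype_matrix()] whose samples carry population labels.
#' @return A [frequency_matrix()] with `n` = genotyped individuals per
#'   population.
#' @export
sample_frequencies <- function(geno) {
  if (any(is.na(geno$samples$population))) {
    abort("every sample must be assigned to a population")
  }
  pops <- unique(geno$samples$population)
  freq <- matrix(NA_real_, length(pops), n_loci(geno))
  n_ind <- integer(length(pops))
  for (i in seq_along(pops)) {
    rows <- geno$samples$population == pops[i]
    dos <- geno$dosage[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(dos))
    if (all(n_obs == 0)) {
      abort(sprintf("population %s has no genotyped individual at any locus",
                    pops[i]))
    }
    f <- colSums(dos, na.rm = TRUE) / (2 * n_obs)
    f[n_obs == 0] <- NA_real_
    freq[i, ] <- f
    n_ind[i] <- sum(rows)
  }
  frequency_matrix(tibble(population = pops, n = n_ind), freq,
                   loci = geno$snps$id)
}

#' Allele frequencies from pooled read counts
#'
#' The pooled estimator: alternative-read proportion `alt_reads / depth` per
#' population per locus; zero-depth loci are flagged missing (`NA`).
#'
#' @param pool A [pool_table()].
#' @return A [frequency_matrix()] with `n` = pooled individuals.
#' @export
pooled_frequencies <- function(pool) {
  freq <- pool$alt_reads / pool$depth
  freq[pool$depth == 0] <- NA_real_
  frequency_matrix(
    tibble(population = pool$populations$population,
           n = pool$populations$n_individuals),
    freq, loci = pool$snps$id
  )
}

#' Allele frequency spectrum
#'
#' Bins frequencies into 40 left-closed bins of width 0.025 over \[0, 1\];
#' the last bin `[0.975, 1]` is closed on both sides, so fixed loci fall in
#' the final bin.
#'
#' @param freqs Numeric vector of allele frequencies in \[0, 1\] (NAs are
#'   dropped).
#' @return An `af_spectrum` tibble with columns `bin_lo`, `bin_hi`, `count`,
#'   `proportion`; the total SNP count is stored in attribute `n_total`.
#' @export
afs <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) && (min(freqs) < 0 || max(freqs) > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  edges <- seq(0, 1, by = 0.025)
  bin <- pmin(floor(freqs / 0.025) + 1L, 40L)
  counts <- tabulate(bin, nbins = 40L)
  out <- tibble(
    bin_lo = edges[-41], bin_hi = edges[-1],
    count = counts,
    proportion = if (length(freqs)) counts / length(freqs) else rep(0, 40)
  )
  structure(out, class = c("af_spectrum", class(out)),
            n_total = length(freqs))
}

#' Mean expected heterozygosity per population
#'
#' Per locus He = 2p(1-p); the per-population value is the mean over the
#' requested loci, excluding loci whose frequency is missing in that
#' population. Monomorphic loci contribute 0.
#'
#' @param freqs A [frequency_matrix()].
#' @param subset Optional character vector of locus ids (default: all loci).
#' @return Tibble with columns `population`, `he`, `n_loci`.
#' @export
expected_heterozygosity <- function(freqs, subset = NULL) {
  cols <- resolve_subset(freqs, subset)
  if (!length(cols)) abort("empty locus subset")
  p <- freqs$freq[, cols, drop = FALSE]
  he_mat <- 2 * p * (1 - p)
  tibble(
    population = freqs$populations$population,
    he = unname(rowMeans(he_mat, na.rm = TRUE)),
    n_loci = unname(rowSums(!is.na(he_mat)))
  )
}

resolve_subset <- function(freqs, subset) {
  if (is.null(subset)) return(seq_along(freqs$loci))
  cols <- which(freqs$loci %in% subset)
  if (length(cols) < length(unique(subset))) {
    missing_n <- length(unique(subset)) - length(cols)
    warn(sprintf("%d subset locus id(s) not present in the frequency matrix",
                 missing_n))
  }
  cols
}

#' Pairwise F_ST between two populations
#'
#' The variance-of-frequencies estimator F_ST = s^2 / (pbar (1 - pbar))
#' computed per locus and averaged across loci. In `"equal"` mode
#' s^2 = sum_i (p_i - pbar)^2 / r with pbar the unweighted mean; in
#' `"weighted"` mode (for unequal sample sizes)
#' s^2 = sum_i n_i (p_i - pbar)^2 / (r nbar) with
#' pbar = sum_i n_i p_i / (r nbar), where r = 2 populations and nbar the mean
#' sample size. Loci with pbar (1 - pbar) = 0 or a missing frequency are
#' excluded.
#'
#' @param freqs A [frequency_matrix()].
#' @param pop_a,pop_b Population labels.
#' @param mode `"weighted"` (default) or `"equal"`.
#' @param subset Optional locus-id subset.
#' @param average `"ratio"` (mean of per-locus ratios, default) or
#'   `"ratio_of_sums"` (sum of s^2 over sum of denominators).
#' @return F_ST as a single number.
#' @export
pairwise_fst <- function(freqs, pop_a, pop_b,
                         mode = c("weighted", "equal"),
                         subset = NULL,
                         average = c("ratio", "ratio_of_sums")) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  labs <- freqs$populations$population
  if (!all(c(pop_a, pop_b) %in% labs)) {
    abort("both populations must be present in the frequency matrix")
  }
  cols <- resolve_subset(freqs, subset)
  p1 <- freqs$freq[match(pop_a, labs), cols]
  p2 <- freqs$freq[match(pop_b, labs), cols]
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  r <- 2
  if (mode == "equal") {
    pbar <- (p1 + p2) / 2
    s2 <- ((p1 - pbar)^2 + (p2 - pbar)^2) / r
  } else {
    n1 <- freqs$populations$n[match(pop_a, labs)]
    n2 <- freqs$populations$n[match(pop_b, labs)]
    nbar <- (n1 + n2) / 2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r * nbar)
  }
  denom <- pbar * (1 - pbar)
  inf <- denom > 0
  if (!any(inf)) abort("no informative loci for this population pair")
  if (average == "ratio") {
    mean(s2[inf] / denom[inf])
  } else {
    sum(s2[inf]) / sum(denom[inf])
  }
}

#' All pairwise F_ST values
#'
#' @inheritParams pairwise_fst
#' @return Tibble with columns `pop_a`, `pop_b`, `fst` for every unordered
#'   population pair.
#' @export
pairwise_fst_all <- function(freqs, mode = c("weighted", "equal"),
                             subset = NULL,
                             average = c("ratio", "ratio_of_sums")) {
  mode <- match.arg(mode)
  average <- match.arg(average)
  labs <- freqs$populations$population
  pairs <- combn(labs, 2)
  tibble(
    pop_a = pairs[1, ], pop_b = pairs[2, ],
    fst = purrr::map2_dbl(pairs[1, ], pairs[2, ], function(a, b) {
      pairwise_fst(freqs, a, b, mode = mode, subset = subset,
                   average = average)
    })
  )
}

#' Nei's standard genetic distance matrix
#'
#' Biallelic specialization of Nei's (1972) standard distance:
#' D = -ln( Jxy / sqrt(Jx Jy) ) with Jx = sum_l (p_l^2 + q_l^2), Jy analogous
#' and Jxy = sum_l (p_xl p_yl + q_xl q_yl), summed over loci with non-missing
#' frequencies in both populations of a pair.
#'
#' @param freqs A [frequency_matrix()] with at least two populations.
#' @param subset Optional locus-id subset.
#' @return Labeled symmetric matrix of distances (zero diagonal). Degenerate
#'   pairs with non-positive identity get `Inf` with a warning.
#' @export
nei_distance_matrix <- function(freqs, subset = NULL) {
  if (nrow(freqs$freq) < 2) abort("need at least two populations")
  cols <- resolve_subset(freqs, subset)
  P <- freqs$freq[, cols, drop = FALSE]
  labs <- freqs$populations$population
  n_pop <- nrow(P)
  d <- matrix(0, n_pop, n_pop, dimnames = list(labs, labs))
  if (!anyNA(P)) {
    Q <- 1 - P
    cross <- P %*% t(P) + Q %*% t(Q)
    j_self <- diag(cross)
    I <- cross / sqrt(outer(j_self, j_self))
    d <- -log(I)
    d[d < 0] <- 0  # guard against -eps from floating-point identity > 1
    diag(d) <- 0
  } else {
    for (x in seq_len(n_pop - 1)) {
      for (y in (x + 1):n_pop) {
        ok <- !is.na(P[x, ]) & !is.na(P[y, ])
        px <- P[x, ok]; py <- P[y, ok]
        jx <- sum(px^2 + (1 - px)^2)
        jy <- sum(py^2 + (1 - py)^2)
        jxy <- sum(px * py + (1 - px) * (1 - py))
        d[x, y] <- d[y, x] <- -log(jxy / sqrt(jx * jy))
      }
    }
  }
  if (any(!is.finite(d))) {
    warn("non-positive genetic identity for some pair(s); distance set to Inf")
    d[is.nan(d)] <- Inf
  }
  d
}

#' PCA of population allele frequencies
#'
#' Singular value decomposition of the column-centered populations x loci
#' frequency matrix. Loci with any missing frequency are dropped first.
#'
#' @param freqs A [frequency_matrix()].
#' @param subset Optional locus-id subset.
#' @param k Number of components to return.
#' @return List with `coordinates` (tibble: population + PC columns) and
#'   `var_explained` (length-k, non-increasing, entries in \[0, 1\], full sum
#'   over all components = 1).
#' @export
pca_frequencies <- function(freqs, subset = NULL, k = 2) {
  cols <- resolve_subset(freqs, subset)
  X <- freqs$freq[, cols, drop = FALSE]
  X <- X[, colSums(is.na(X)) == 0, drop = FALSE]
  if (nrow(X) < 2 || ncol(X) < k) {
    abort("need >= 2 populations and >= k complete loci")
  }
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  rank <- sum(pr$sdev^2 > tot * 1e-12)
  if (k > rank) abort(sprintf("k = %d exceeds rank %d", k, rank))
  coords <- as_tibble(pr$x[, seq_len(k), drop = FALSE])
  coords <- dplyr::bind_cols(
    tibble(population = freqs$populations$population), coords
  )
  list(coordinates = coords,
       var_explained = (pr$sdev^2 / tot)[seq_len(k)])
}

#' PCA of individual dosages
#'
#' Exploration mode for array-only data: PCA of mean-imputed, column-centered
#' individual dosage vectors.
#'
#' @param geno A [genotype_matrix()].
#' @param k Number of components.
#' @return As [pca_frequencies()], with one row per individual plus its
#'   population label.
#' @export
pca_genotypes <- function(geno, k = 2) {
  X <- geno$dosage
  cm <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- cm[j]
  X <- X[, apply(X, 2, var) > 0, drop = FALSE]
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  rank <- sum(pr$sdev^2 > tot * 1e-12)
  if (k > rank) abort(sprintf("k = %d exceeds rank %d", k, rank))
  coords <- as_tibble(pr$x[, seq_len(k), drop = FALSE])
  coords <- dplyr::bind_cols(
    tibble(sample_id = geno$samples$sample_id,
           population = geno$samples$population),
    coords
  )
  list(coordinates = coords,
       var_explained = (pr$sdev^2 / tot)[seq_len(k)])
}

#' Classify SNPs as genic or non-genic
#'
#' A SNP is genic iff its position overlaps any gene interval (1-based,
#' inclusive on both ends). Intervals may be a GFF3/BED file path (read via
#' rtracklayer), a data frame with columns `chromosome`, `start`, `end`, or a
#' `GRanges`. Chromosome names are matched after stripping an optional "chr"
#' prefix.
#'
#' @param snps SNP table (as in [genotype_matrix()]) or a `geno_matrix`.
#' @param intervals Gene intervals (path, data frame or GRanges).
#' @param freqs Optional named frequency vector (names = SNP ids); when given,
#'   per-class MAF spectra are returned as well.
#' @return List with `classes` (tibble: `id`, `genic`) and, when `freqs` is
#'   supplied, `spectra` (list of two [afs()] objects).
#' @export
genic_classification <- function(snps, intervals, freqs = NULL) {
  if (inherits(snps, "geno_matrix")) snps <- snps$snps
  snps <- validate_snp_table(snps)
  gr_genes <- as_gene_ranges(intervals)
  gr_snps <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(snps$chromosome),
    ranges = IRanges::IRanges(start = snps$position, width = 1L)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_snps, gr_genes, ignore.strand = TRUE)
  )
  genic <- seq_len(nrow(snps)) %in% S4Vectors::queryHits(hits)
  out <- list(classes = tibble(id = snps$id, genic = genic))
  if (!is.null(freqs)) {
    f <- freqs[snps$id]
    maf <- pmin(f, 1 - f)
    out$spectra <- list(
      genic = afs(maf[genic]),
      non_genic = afs(maf[!genic])
    )
  }
  out
}

as_gene_ranges <- function(intervals) {
  if (methods::is(intervals, "GRanges")) {
    gr <- intervals
  } else if (is.character(intervals) && length(intervals) == 1L) {
    stop_if_missing_file(intervals, "annotation")
    gr <- rtracklayer::import(intervals)
  } else if (is.data.frame(intervals)) {
    if (nrow(intervals) == 0) {
      return(GenomicRanges::GRanges())
    }
    if (!all(c("chromosome", "start", "end") %in% names(intervals))) {
      abort("interval data frame needs columns chromosome, start, end")
    }
    if (any(intervals$end < intervals$start)) {
      abort("malformed interval: end < start")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(intervals$chromosome),
      ranges = IRanges::IRanges(start = intervals$start, end = intervals$end)
    )
  } else {
    abort("unsupported interval input")
  }
  strip_chr_prefix(gr)
}

# Strip "chr" prefixes on a GRanges without renaming seqlevels in place.
strip_chr_prefix <- function(gr) {
  if (!length(gr)) return(gr)
  GenomicRanges::GRanges(
    seqnames = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
    ranges = IRanges::ranges(gr)
  )
}
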