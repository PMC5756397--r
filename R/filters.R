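#' Filtering configuration
#'
#' Bundles the thresholds of the quality-control and mitigation filters.
#' Defaults mirror common array practice: SNP call rate > 0.99, animal call
#' rate > 0.95, MAF cutoff 0.05, and LD pruning with a 50-SNP window, 5-SNP
#' step and variance inflation factor 2 (i.e. r-squared threshold
#' 1 - 1/VIF = 0.5).
#'
#' @param snp_call_rate_min,sample_call_rate_min Call-rate thresholds in
#'   \[0, 1\]; SNPs/samples are retained only if their call rate is *strictly
#'   greater* than the threshold.
#' @param maf_min MAF threshold; SNPs with `min(p, 1-p) >= maf_min` are kept.
#' @param ld_window_snps,ld_step_snps Window size and step, in SNPs.
#' @param vif_max Variance inflation factor bound (> 1); in pairwise mode the
#'   induced r-squared threshold is `1 - 1/vif_max`.
#' @param ld_mode `"pairwise"` (remove the lower-MAF member of correlated
#'   pairs) or `"vif"` (multiple-regression variance inflation).
#' @param reference_populations Populations whose polymorphism defines the
#'   wild-polymorphism ("GG") filter.
#' @return A `filter_config` list.
#' @export
filter_config <- function(snp_call_rate_min = 0.99,
                          sample_call_rate_min = 0.95,
                          maf_min = 0.05,
                          ld_window_snps = 50L,
                          ld_step_snps = 5L,
                          vif_max = 2,
                          ld_mode = c("pairwise", "vif"),
                          reference_populations = character()) {
  ld_mode <- match.arg(ld_mode)
  stopifnot(
    snp_call_rate_min >= 0, snp_call_rate_min <= 1,
    sample_call_rate_min >= 0, sample_call_rate_min <= 1,
    maf_min >= 0, maf_min <= 1,
    ld_window_snps > ld_step_snps, ld_step_snps >= 1,
    vif_max > 1
  )
  structure(list(
    snp_call_rate_min = snp_call_rate_min,
    sample_call_rate_min = sample_call_rate_min,
    maf_min = maf_min,
    ld_window_snps = as.integer(ld_window_snps),
    ld_step_snps = as.integer(ld_step_snps),
    vif_max = vif_max,
    ld_mode = ld_mode,
    reference_populations = reference_populations
  ), class = "filter_config")
}

#' Call-rate quality control
#'
#' Drops SNPs whose call rate is not strictly above `snp_call_rate_min`, then
#' samples whose call rate is not strictly above `sample_call_rate_min`.
#'
#' @param geno A [genotype_matrix()].
#' @param cfg A [filter_config()].
#' @return List with the filtered `genotypes` and a one-row `log` tibble.
#' @export
qc_filter <- function(geno, cfg = filter_config()) {
  if (n_loci(geno) == 0) abort("empty genotype matrix")
  snp_cr <- colMeans(!is.na(geno$dosage))
  keep_snp <- snp_cr > cfg$snp_call_rate_min
  if (!any(keep_snp)) abort("call-rate filter removed every SNP")
  dos <- geno$dosage[, keep_snp, drop = FALSE]
  sample_cr <- rowMeans(!is.na(dos))
  keep_sample <- sample_cr > cfg$sample_call_rate_min
  if (!any(keep_sample)) abort("call-rate filter removed every sample")
  out <- genotype_matrix(geno$snps[keep_snp, ],
                         geno$samples[keep_sample, ],
                         dos[keep_sample, , drop = FALSE])
  list(
    genotypes = out,
    log = tibble(snps_removed = sum(!keep_snp),
                 samples_removed = sum(!keep_sample),
                 snps_retained = sum(keep_snp),
                 samples_retained = sum(keep_sample))
  )
}

# Overall alternative-allele frequency per SNP: pooled over all samples for a
# genotype matrix, sample-size weighted over populations for a freq_matrix.
overall_alt_freq <- function(x) {
  if (inherits(x, "geno_matrix")) {
    n_obs <- colSums(!is.na(x$dosage))
    colSums(x$dosage, na.rm = TRUE) / (2 * n_obs)
  } else if (inherits(x, "freq_matrix")) {
    w <- x$populations$n
    apply(x$freq, 2, function(p) {
      ok <- !is.na(p)
      if (!any(ok)) return(NA_real_)
      sum(w[ok] * p[ok]) / sum(w[ok])
    })
  } else {
    abort("need a geno_matrix or freq_matrix")
  }
}

#' Minor allele frequency filter
#'
#' Retains SNPs with `min(p, 1-p) >= maf_min`, where `p` is the overall
#' alternative-allele frequency across all samples (genotype input) or the
#' sample-size-weighted mean frequency across populations (frequency input).
#'
#' @param x A [genotype_matrix()] or [frequency_matrix()].
#' @param maf_min MAF threshold.
#' @return Character vector of retained SNP ids (input order preserved).
#' @export
maf_filter <- function(x, maf_min = 0.05) {
  p <- overall_alt_freq(x)
  maf <- pmin(p, 1 - p)
  ids <- if (inherits(x, "geno_matrix")) x$snps$id else x$loci
  keep <- !is.na(maf) & maf >= maf_min
  if (!any(keep)) warn("MAF filter retained no SNPs")
  ids[keep]
}

#' Retain SNPs polymorphic in reference (wild) populations
#'
#' Mirrors the strategy of keeping only SNPs that segregate in wild
#' populations not used for array design. By default polymorphism is judged
#' in the pooled sample of all listed populations; `mode = "each"` requires
#' 0 < p < 1 in every population, `mode = "any"` in at least one.
#'
#' @param geno A [genotype_matrix()].
#' @param reference_populations Population labels.
#' @param mode Polymorphism rule: "pooled" (default), "each" or "any".
#' @return Character vector of retained SNP ids.
#' @export
polymorphic_in_reference <- function(geno, reference_populations,
                                     mode = c("pooled", "each", "any")) {
  mode <- match.arg(mode)
  pops <- unique(geno$samples$population)
  unknown <- setdiff(reference_populations, pops)
  if (length(unknown)) {
    abort(paste0("unknown population(s): ", paste(unknown, collapse = ", ")))
  }
  in_ref <- geno$samples$population %in% reference_populations
  if (mode == "pooled") {
    dos <- geno$dosage[in_ref, , drop = FALSE]
    n_obs <- colSums(!is.na(dos))
    p <- colSums(dos, na.rm = TRUE) / (2 * n_obs)
    keep <- !is.na(p) & p > 0 & p < 1
  } else {
    per_pop <- vapply(reference_populations, function(pp) {
      dos <- geno$dosage[geno$samples$population == pp, , drop = FALSE]
      n_obs <- colSums(!is.na(dos))
      p <- colSums(dos, na.rm = TRUE) / (2 * n_obs)
      !is.na(p) & p > 0 & p < 1
    }, logical(n_loci(geno)))
    if (is.null(dim(per_pop))) per_pop <- matrix(per_pop, nrow = 1)
    keep <- if (mode == "each") rowSums(per_pop) == length(reference_populations)
      else rowSums(per_pop) > 0
  }
  geno$snps$id[keep]
}

#' LD-based SNP pruning
#'
#' Slides a window of `ld_window_snps` SNPs along each chromosome, advancing
#' `ld_step_snps` retained SNPs at a time. In the default pairwise mode,
#' while any retained pair within the window has squared dosage correlation
#' above `1 - 1/vif_max`, the member with the lower MAF is removed (ties:
#' the later-positioned SNP). In `"vif"` mode the SNP whose variance
#' inflation factor from multiple regression on the other retained window
#' SNPs exceeds `vif_max` is removed instead, largest first. Correlations use
#' pairwise-complete observations.
#'
#' Window passes are repeated until no further SNP is removed, finishing with
#' unit-step verification sweeps: removals late in a pass can pull previously
#' distant SNPs into a common window (population structure induces long-range
#' dosage correlation between physically unlinked loci), so a single pass
#' does not guarantee the window contract globally. At the returned fixpoint
#' no retained pair within any `ld_window_snps`-SNP window of consecutive
#' retained SNPs violates the threshold, and pruning is idempotent.
#'
#' @param geno A [genotype_matrix()] with SNPs sorted by
#'   (chromosome, position).
#' @param cfg A [filter_config()].
#' @return Character vector of retained SNP ids, in input order.
#' @export
ld_prune <- function(geno, cfg = filter_config()) {
  snps <- geno$snps
  ord <- locus_order(snps$chromosome, snps$position)
  if (!identical(ord, seq_len(nrow(snps)))) {
    abort("SNPs must be sorted by (chromosome, position); sort the input first")
  }
  thr <- 1 - 1 / cfg$vif_max
  p <- overall_alt_freq(geno)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, nrow(snps))
  for (chrom in unique(snps$chromosome)) {
    current <- which(snps$chromosome == chrom)
    one_pass <- function(current, step) {
      removed_all <- integer()
      i <- 1L
      while (i < length(current)) {
        win <- current[i:min(i + cfg$ld_window_snps - 1L, length(current))]
        removed <- if (cfg$ld_mode == "pairwise") {
          clean_window_pairwise(geno$dosage, win, maf, thr)
        } else {
          clean_window_vif(geno$dosage, win, maf, cfg$vif_max)
        }
        if (length(removed)) {
          removed_all <- c(removed_all, removed)
          current <- setdiff(current, removed)
        }
        i <- i + step
      }
      list(current = current, removed = removed_all)
    }
    repeat {
      res <- one_pass(current, cfg$ld_step_snps)
      current <- res$current
      if (!length(res$removed)) break
      keep[res$removed] <- FALSE
    }
    if (cfg$ld_mode == "pairwise") {
      # Verification sweeps: resolve any remaining pair within a window-width
      # of consecutive retained SNPs (equivalently at retained distance
      # < ld_window_snps), worst pair first.
      repeat {
        viol <- near_pair_violations(geno$dosage, current,
                                     cfg$ld_window_snps - 1L, thr)
        if (!nrow(viol)) break
        viol <- viol[order(-viol$r2, viol$a, viol$b), , drop = FALSE]
        gone <- integer()
        for (q in seq_len(nrow(viol))) {
          a <- viol$a[q]; b <- viol$b[q]
          if (a %in% gone || b %in% gone) next
          drop_snp <- if (maf[a] < maf[b]) a
            else if (maf[b] < maf[a]) b
            else max(a, b)
          gone <- c(gone, drop_snp)
        }
        keep[gone] <- FALSE
        current <- setdiff(current, gone)
      }
    } else {
      repeat {
        res <- one_pass(current, 1L)
        current <- res$current
        if (!length(res$removed)) break
        keep[res$removed] <- FALSE
      }
    }
  }
  snps$id[keep]
}

# Squared pairwise-complete Pearson correlation between dosage columns
# `cols[j]` and `cols[j + d]`, vectorized over j via masked cross-products.
offset_r2 <- function(dosage, cols, d) {
  L <- length(cols)
  a <- seq_len(L - d); b <- a + d
  Xa <- dosage[, cols[a], drop = FALSE]
  Xb <- dosage[, cols[b], drop = FALSE]
  Ma <- !is.na(Xa); Mb <- !is.na(Xb)
  Xa[!Ma] <- 0L; Xb[!Mb] <- 0L
  storage.mode(Xa) <- "double"; storage.mode(Xb) <- "double"
  Ma <- Ma * 1; Mb <- Mb * 1
  n <- colSums(Ma * Mb)
  sx <- colSums(Xa * Mb)
  sy <- colSums(Xb * Ma)
  sxy <- colSums(Xa * Xb)
  sxx <- colSums(Xa * Xa * Mb)
  syy <- colSums(Xb * Xb * Ma)
  num <- n * sxy - sx * sy
  den <- (n * sxx - sx^2) * (n * syy - sy^2)
  r2 <- numeric(L - d)
  ok <- den > 0 & n >= 2
  r2[ok] <- num[ok]^2 / den[ok]
  r2
}

# All pairs of retained columns at retained distance <= maxdist whose r^2
# exceeds `thr`; returns global column indices a < b.
near_pair_violations <- function(dosage, current, maxdist, thr) {
  out <- list()
  for (d in seq_len(min(maxdist, length(current) - 1L))) {
    r2 <- offset_r2(dosage, current, d)
    hit <- which(r2 > thr)
    if (length(hit)) {
      out[[length(out) + 1L]] <- tibble(
        a = current[hit], b = current[hit + d], r2 = r2[hit]
      )
    }
  }
  if (!length(out)) {
    return(tibble(a = integer(), b = integer(), r2 = numeric()))
  }
  dplyr::bind_rows(out)
}

# Remove SNPs from one window until no retained pair exceeds the r^2
# threshold; returns the removed (global) column indices.
clean_window_pairwise <- function(dosage, win, maf, thr) {
  removed <- integer()
  while (length(win) >= 2L) {
    r2 <- suppressWarnings(
      cor(dosage[, win, drop = FALSE], use = "pairwise.complete.obs")
    )^2
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    if (max(r2) <= thr) break
    # Deterministic order: resolve the strongest pair first; ties by the
    # earliest (row, col) position.
    hit <- which(r2 == max(r2), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    a <- win[hit[1, 1]]; b <- win[hit[1, 2]]
    drop_snp <- if (maf[a] < maf[b]) a
      else if (maf[b] < maf[a]) b
      else max(a, b)  # tie: remove the later-positioned SNP
    removed <- c(removed, drop_snp)
    win <- setdiff(win, drop_snp)
  }
  removed
}

clean_window_vif <- function(dosage, win, maf, vif_max) {
  removed <- integer()
  while (length(win) >= 2L) {
    r <- suppressWarnings(
      cor(dosage[, win, drop = FALSE], use = "pairwise.complete.obs")
    )
    r[!is.finite(r)] <- 0
    diag(r) <- 1
    inv <- tryCatch(solve(r), error = function(e) NULL)
    if (is.null(inv)) {
      # Singular correlation matrix: a perfectly collinear pair is present.
      r2 <- r^2; diag(r2) <- 0
      hit <- which(r2 == max(r2), arr.ind = TRUE)
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      a <- win[hit[1, 1]]; b <- win[hit[1, 2]]
      drop_snp <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
    } else {
      vif <- diag(inv)
      if (max(vif) <= vif_max) break
      worst <- which(vif == max(vif))
      drop_snp <- max(win[worst])  # largest VIF; ties -> later SNP
    }
    removed <- c(removed, drop_snp)
    win <- setdiff(win, drop_snp)
  }
  removed
}

#' Post-hoc check of the LD pruning contract
#'
#' Scans every window of `ld_window_snps` consecutive retained SNPs (all start
#' offsets, per chromosome) and reports the largest within-window pairwise
#' r-squared.
#'
#' @param geno A [genotype_matrix()].
#' @param subset Retained SNP ids.
#' @param cfg A [filter_config()].
#' @return List with `max_r2` and `clean` (TRUE if `max_r2 <= 1 - 1/vif_max`).
#' @export
ld_prune_check <- function(geno, subset, cfg = filter_config()) {
  thr <- 1 - 1 / cfg$vif_max
  keep <- geno$snps$id %in% subset
  snps <- geno$snps[keep, ]
  dos <- geno$dosage[, keep, drop = FALSE]
  worst <- 0
  for (chrom in unique(snps$chromosome)) {
    idx <- which(snps$chromosome == chrom)
    if (length(idx) < 2) next
    # a pair shares a 50-SNP window iff its retained distance is < 50
    for (d in seq_len(min(cfg$ld_window_snps - 1L, length(idx) - 1L))) {
      worst <- max(worst, offset_r2(dos, idx, d))
    }
  }
  list(max_r2 = worst, clean = worst <= thr + 1e-12)
}

#' Build the eight filtered dataset versions
#'
#' Applies the three mitigation filters alone and in combination:
#' `Array_all`, `Array_MAF5`, `GG`, `GG_MAF5`, `Pruned`, `Pruned_MAF5`,
#' `Pruned_GG`, `Pruned_GG_MAF5`. Composition order is prune-then-GG, with
#' the MAF filter always applied last. ("GG" refers to the wild
#' reference-population polymorphism filter; "MAF5" to the `maf_min`
#' cutoff, 0.05 by default.)
#'
#' @param geno A harmonized [genotype_matrix()].
#' @param cfg A [filter_config()]; `reference_populations` may be empty, in
#'   which case the GG filter is a no-op.
#' @return Named list of SNP-id character vectors, all subsets of
#'   `geno$snps$id` in input order.
#' @export
build_versions <- function(geno, cfg = filter_config()) {
  all_ids <- geno$snps$id
  maf_ids <- if (cfg$maf_min > 0) maf_filter(geno, cfg$maf_min) else all_ids
  gg_ids <- if (length(cfg$reference_populations)) {
    polymorphic_in_reference(geno, cfg$reference_populations)
  } else all_ids
  pruned_ids <- if (is.finite(cfg$vif_max)) ld_prune(geno, cfg) else all_ids
  keep_order <- function(ids) all_ids[all_ids %in% ids]
  list(
    Array_all = all_ids,
    Array_MAF5 = keep_order(maf_ids),
    GG = keep_order(gg_ids),
    GG_MAF5 = keep_order(intersect(gg_ids, maf_ids)),
    Pruned = keep_order(pruned_ids),
    Pruned_MAF5 = keep_order(intersect(pruned_ids, maf_ids)),
    Pruned_GG = keep_order(intersect(pruned_ids, gg_ids)),
    Pruned_GG_MAF5 = keep_order(Reduce(intersect,
                                       list(pruned_ids, gg_ids, maf_ids)))
  )
}
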