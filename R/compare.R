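#' Draw replicate SNP subsets from a reference locus set
#'
#' Replicate `r` is drawn without replacement from `reference_loci` using the
#' deterministic stream `seed + r`, so replicates are reproducible and
#' mutually independent.
#'
#' @param reference_loci Character vector of locus ids.
#' @param n_snps Number of loci per replicate (`<= length(reference_loci)`).
#' @param n_replicates Number of replicates.
#' @param seed Integer base seed.
#' @return A `replicate_set`: list of locus-id vectors with attributes
#'   `n_snps`, `n_replicates`, `seed`.
#' @export
draw_replicates <- function(reference_loci, n_snps, n_replicates, seed) {
  if (n_snps > length(reference_loci)) {
    abort(sprintf("n_snps (%d) exceeds the reference locus count (%d)",
                  n_snps, length(reference_loci)))
  }
  reps <- lapply(seq_len(n_replicates), function(r) {
    withr::with_seed(as.integer(seed + r), sample(reference_loci, n_snps))
  })
  structure(reps, class = "replicate_set",
            n_snps = n_snps, n_replicates = n_replicates, seed = seed)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. A constant vector makes the
#' correlation undefined; `NA` is returned in that case.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Ordinary least squares summary
#'
#' Regresses `y` on `x` and returns the slope, intercept (regression
#' constant), R-squared, the standard error of the slope and the residual
#' variance RSS / (n - 2).
#'
#' @param y Response values.
#' @param x Predictor values.
#' @return One-row tibble with columns `slope`, `intercept`, `r_squared`,
#'   `slope_se`, `residual_variance`, `n`.
#' @export
regress <- function(y, x) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (var(x) == 0) abort("zero predictor variance")
  fit <- lm(y ~ x)
  # summary.lm warns on exactly collinear input ("essentially perfect fit");
  # that is a legitimate case here (self-comparisons), not a defect.
  s <- suppressWarnings(summary(fit))
  n <- length(x)
  tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    slope_se = s$coefficients[2, 2],
    residual_variance = sum(stats::residuals(fit)^2) / (n - 2),
    n = n
  )
}

#' Run the full array-versus-reference comparison
#'
#' For each filtered array version: (1) per-population expected
#' heterozygosity from the array subset versus the full reference, with
#' Spearman rank correlation and an OLS regression; (2) pairwise F_ST
#' regression over all population pairs; (3) Frobenius distance between the
#' array Nei matrix and Nei matrices of `n_replicates` reference subsets of
#' matching SNP count (mean and standard error); (4) neighbor-joining tree
#' partition and branch-score distances likewise, plus
#' replicate-versus-replicate baseline distributions; (5) PCA variance
#' explained for both datasets.
#'
#' The array loci must be a subset of the reference loci: replicates and the
#' reference-side statistics are computed on the full reference locus set,
#' the array-side statistics on each version's subset.
#'
#' @param array A [genotype_matrix()] (the harmonized array data).
#' @param reference A [pool_table()] covering all reference loci.
#' @param versions Named list of SNP-id vectors, e.g. from [build_versions()].
#' @param n_replicates Number of reference replicates per version.
#' @param seed Integer seed controlling replicate draws and baseline
#'   subsampling.
#' @param fst_mode `"weighted"` (default) or `"equal"`.
#' @param orientation `"array_on_reference"` (array statistic is the
#'   response; default) or `"reference_on_array"`.
#' @param max_baseline_pairs Replicate-pair baselines are subsampled to this
#'   many pairs when the number of pairs exceeds it.
#' @return A `comparison_report` (see [tidy.comparison_report()] and
#'   [glance.comparison_report()]).
#' @export
run_comparison <- function(array, reference, versions,
                           n_replicates = 100, seed = 1,
                           fst_mode = c("weighted", "equal"),
                           orientation = c("array_on_reference",
                                           "reference_on_array"),
                           max_baseline_pairs = 1000) {
  fst_mode <- match.arg(fst_mode)
  orientation <- match.arg(orientation)
  if (!length(versions)) abort("`versions` must be non-empty")
  pops_a <- sort(unique(array$samples$population))
  pops_r <- sort(reference$populations$population)
  if (!identical(pops_a, pops_r)) {
    abort("array and reference must cover the same populations")
  }
  ref_loci <- reference$snps$id
  missing_loci <- setdiff(array$snps$id, ref_loci)
  if (length(missing_loci)) {
    abort(sprintf("%d array loci are absent from the reference",
                  length(missing_loci)))
  }

  freq_arr <- sample_frequencies(array)
  freq_ref <- pooled_frequencies(reference)
  he_ref <- expected_heterozygosity(freq_ref)
  fst_ref <- pairwise_fst_all(freq_ref, mode = fst_mode)
  pca_ref <- pca_frequencies(freq_ref, k = 2)

  pick <- function(resp, pred) {
    if (orientation == "array_on_reference") regress(resp, pred)
    else regress(pred, resp)
  }

  version_blocks <- purrr::imap(versions, function(sub, vname) {
    v_idx <- match(vname, names(versions))
    he_arr <- expected_heterozygosity(freq_arr, subset = sub)
    he_tab <- dplyr::inner_join(
      dplyr::rename(he_arr, he_array = "he", n_loci_array = "n_loci"),
      dplyr::rename(he_ref, he_reference = "he", n_loci_reference = "n_loci"),
      by = "population"
    )
    rho <- spearman_rho(he_tab$he_array, he_tab$he_reference)
    he_reg <- pick(he_tab$he_array, he_tab$he_reference)

    fst_arr <- pairwise_fst_all(freq_arr, mode = fst_mode, subset = sub)
    fst_tab <- dplyr::inner_join(
      dplyr::rename(fst_arr, fst_array = "fst"),
      dplyr::rename(fst_ref, fst_reference = "fst"),
      by = c("pop_a", "pop_b")
    )
    fst_reg <- pick(fst_tab$fst_array, fst_tab$fst_reference)

    nei_arr <- nei_distance_matrix(freq_arr, subset = sub)
    tree_arr <- neighbor_joining(nei_arr)
    reps <- draw_replicates(ref_loci, length(sub), n_replicates,
                            substream_seed(seed, paste0("replicates_", vname)) %% 2000000000)
    rep_nei <- lapply(reps, function(l) nei_distance_matrix(freq_ref, subset = l))
    rep_tree <- lapply(rep_nei, neighbor_joining)

    frob <- vapply(rep_nei, frobenius_distance, numeric(1), a = nei_arr)
    part <- vapply(rep_tree, partition_distance, numeric(1), a = tree_arr)
    bl <- vapply(rep_tree, function(t) as.numeric(branch_length_distance(tree_arr, t)),
                 numeric(1))

    prs <- baseline_pairs(n_replicates, max_baseline_pairs,
                          substream_seed(seed, paste0("baseline_", vname)))
    base_frob <- vapply(seq_len(ncol(prs)), function(q) {
      frobenius_distance(rep_nei[[prs[1, q]]], rep_nei[[prs[2, q]]])
    }, numeric(1))
    base_part <- vapply(seq_len(ncol(prs)), function(q) {
      as.numeric(partition_distance(rep_tree[[prs[1, q]]], rep_tree[[prs[2, q]]]))
    }, numeric(1))
    base_bl <- vapply(seq_len(ncol(prs)), function(q) {
      as.numeric(branch_length_distance(rep_tree[[prs[1, q]]], rep_tree[[prs[2, q]]]))
    }, numeric(1))

    pca_arr <- pca_frequencies(freq_arr, subset = sub, k = 2)

    list(
      n_snps = length(sub),
      he = list(table = he_tab, spearman_rho = rho, regression = he_reg),
      fst = list(table = fst_tab, regression = fst_reg),
      frobenius = dist_summary(frob, base_frob),
      tree = list(partition = dist_summary(part, base_part),
                  branch_score = dist_summary(bl, base_bl)),
      pca = list(var_explained_array = pca_arr$var_explained,
                 var_explained_reference = pca_ref$var_explained)
    )
  })

  structure(
    list(
      versions = version_blocks,
      populations = pops_a,
      n_replicates = n_replicates,
      seed = seed,
      fst_mode = fst_mode,
      orientation = orientation
    ),
    class = "comparison_report"
  )
}

dist_summary <- function(values, baseline) {
  list(
    mean = mean(values),
    se = sd(values) / sqrt(length(values)),
    values = values,
    baseline_mean = mean(baseline),
    baseline_se = sd(baseline) / sqrt(length(baseline)),
    baseline_values = baseline
  )
}

baseline_pairs <- function(n_reps, max_pairs, seed) {
  all_pairs <- combn(n_reps, 2)
  if (ncol(all_pairs) > max_pairs) {
    pick <- withr::with_seed(as.integer(seed %% 2000000000),
                             sample(ncol(all_pairs), max_pairs))
    all_pairs <- all_pairs[, sort(pick), drop = FALSE]
  }
  all_pairs
}

#' Serialize / read a comparison report as JSON
#'
#' @param report A `comparison_report`.
#' @param path Output (input) path.
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   reconstructed report.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  stop_if_missing_file(path, "report")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$versions <- lapply(raw$versions, function(v) {
    v$he$table <- as_tibble(as.data.frame(v$he$table))
    v$he$regression <- as_tibble(as.data.frame(v$he$regression))
    v$fst$table <- as_tibble(as.data.frame(v$fst$table))
    v$fst$regression <- as_tibble(as.data.frame(v$fst$regression))
    v
  })
  structure(raw, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d version(s), %d populations, %d replicates\n",
              length(x$versions), length(x$populations), x$n_replicates))
  print(glance(x))
  invisible(x)
}

#' Tidy a comparison report into a long tibble
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return Tibble with columns `version`, `statistic`, `value`.
#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  purrr::imap_dfr(x$versions, function(v, vname) {
    tibble(
      version = vname,
      statistic = c(
        "n_snps", "he_spearman_rho", "he_slope", "he_intercept",
        "he_r_squared", "fst_slope", "fst_intercept", "fst_r_squared",
        "fst_slope_se", "fst_residual_variance",
        "frobenius_mean", "frobenius_se",
        "frobenius_baseline_mean",
        "partition_mean", "partition_se", "partition_baseline_mean",
        "branch_score_mean", "branch_score_se", "branch_score_baseline_mean",
        "pca_var2_array", "pca_var2_reference"
      ),
      value = c(
        v$n_snps, v$he$spearman_rho, v$he$regression$slope,
        v$he$regression$intercept, v$he$regression$r_squared,
        v$fst$regression$slope, v$fst$regression$intercept,
        v$fst$regression$r_squared, v$fst$regression$slope_se,
        v$fst$regression$residual_variance,
        v$frobenius$mean, v$frobenius$se, v$frobenius$baseline_mean,
        v$tree$partition$mean, v$tree$partition$se,
        v$tree$partition$baseline_mean,
        v$tree$branch_score$mean, v$tree$branch_score$se,
        v$tree$branch_score$baseline_mean,
        sum(v$pca$var_explained_array[1:2]),
        sum(v$pca$var_explained_reference[1:2])
      )
    )
  })
}

#' One-row-per-version summary of a comparison report
#'
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @return Tibble with one row per filtered version and the headline
#'   statistics as columns.
#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tidy(x) |>
    tidyr::pivot_wider(names_from = "statistic", values_from = "value") |>
    dplyr::select("version", "n_snps", "he_spearman_rho", "he_slope",
                  "fst_slope", "fst_r_squared", "frobenius_mean",
                  "partition_mean", "branch_score_mean",
                  dplyr::everything())
}
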