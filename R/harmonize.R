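#' Harmonize array genotypes with a pooled reference
#'
#' Reconciles the two data sources into locus-matched, allele-matched sets by
#' applying, in order: (1) drop array SNPs with missing/undefined positions;
#' (2) within each dataset, drop *all* SNPs sharing a (chromosome, position)
#' pair (both members removed); (3) keep loci present in both datasets and on
#' `allowed_chromosomes`; (4) drop loci whose ref or alt allele disagrees
#' between the datasets. Chromosome names are compared after stripping an
#' optional "chr" prefix. No strand flipping is attempted: mismatched alleles
#' are dropped, not repaired.
#'
#' @param array A [genotype_matrix()].
#' @param reference A [pool_table()].
#' @param allowed_chromosomes Character vector of chromosome names to keep
#'   (compared after prefix stripping). Defaults to `"1"` ... `"28"`; use
#'   `NULL` to keep every chromosome.
#' @return A list with elements `array`, `reference` (locus lists identical in
#'   content and order) and `log`, a tibble of per-step removal counts.
#' @export
harmonize <- function(array, reference, allowed_chromosomes = as.character(1:28)) {
  if (!inherits(array, "geno_matrix")) abort("`array` must be a geno_matrix")
  if (!inherits(reference, "pool_table")) abort("`reference` must be a pool_table")
  if (n_loci(array) == 0 || n_loci(reference) == 0) {
    abort("both inputs must be non-empty")
  }
  log <- list()
  note <- function(step, what, rem_a, rem_r) {
    tibble(step = step, description = what,
           removed_array = rem_a, removed_reference = rem_r)
  }

  # Step 1: missing positions (array side; the reference table requires them).
  a_keep <- !is.na(array$snps$position)
  r_keep <- !is.na(reference$snps$position)
  log[[1]] <- note(1L, "missing position", sum(!a_keep), sum(!r_keep))
  a_snps <- array$snps[a_keep, ]
  r_snps <- reference$snps[r_keep, ]

  # Step 2: duplicated (chromosome, position) within a dataset; both removed.
  a_key <- locus_key(a_snps$chromosome, a_snps$position)
  r_key <- locus_key(r_snps$chromosome, r_snps$position)
  a_dup <- a_key %in% a_key[duplicated(a_key)]
  r_dup <- r_key %in% r_key[duplicated(r_key)]
  log[[2]] <- note(2L, "duplicated position (both members removed)",
                   sum(a_dup), sum(r_dup))
  a_snps <- a_snps[!a_dup, ]; a_key <- a_key[!a_dup]
  r_snps <- r_snps[!r_dup, ]; r_key <- r_key[!r_dup]

  # Step 3: shared loci on allowed chromosomes.
  shared <- intersect(a_key, r_key)
  if (!is.null(allowed_chromosomes)) {
    allowed <- normalize_chrom(allowed_chromosomes)
    chrom_of <- sub(":.*$", "", shared)
    shared <- shared[chrom_of %in% allowed]
  }
  a_in <- a_key %in% shared
  r_in <- r_key %in% shared
  log[[3]] <- note(3L, "not shared or not on an allowed chromosome",
                   sum(!a_in), sum(!r_in))
  if (!length(shared)) {
    abort("harmonization emptied the locus set at step 3 (shared loci)",
          class = "ascbias_empty_intersection")
  }
  a_snps <- a_snps[a_in, ]; a_key <- a_key[a_in]
  r_snps <- r_snps[r_in, ]; r_key <- r_key[r_in]

  # Step 4: allele agreement at shared loci.
  r_at <- r_snps[match(a_key, r_key), ]
  agree <- a_snps$ref_allele == r_at$ref_allele &
    a_snps$alt_allele == r_at$alt_allele
  log[[4]] <- note(4L, "ref/alt allele mismatch", sum(!agree), sum(!agree))
  if (!any(agree)) {
    abort("harmonization emptied the locus set at step 4 (allele match)",
          class = "ascbias_empty_intersection")
  }
  a_snps <- a_snps[agree, ]
  keep_key <- locus_key(a_snps$chromosome, a_snps$position)

  out_array <- subset_loci(array, a_snps$id)
  ref_ids <- r_snps$id[match(keep_key, r_key)]
  out_ref <- subset_loci(reference, ref_ids)

  # Reference columns follow the array order (both already position-sorted
  # within their own constructors, but enforce identical ordering anyway).
  ord <- match(keep_key,
               locus_key(out_ref$snps$chromosome, out_ref$snps$position))
  out_ref <- pool_table(out_ref$snps[ord, ], out_ref$populations,
                        out_ref$alt_reads[, ord, drop = FALSE],
                        out_ref$depth[, ord, drop = FALSE])

  list(array = out_array, reference = out_ref,
       log = dplyr::bind_rows(log))
}

#' Write a harmonization log as JSON
#'
#' @param log The `log` tibble returned by [harmonize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
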