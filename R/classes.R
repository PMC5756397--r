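#' Construct a genotype matrix
#'
#' The "array" side of the pipeline: individually genotyped samples with
#' alternative-allele dosages in \{0, 1, 2\} (NA = missing call).
#'
#' @param snps Tibble/data frame with columns `id`, `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`; one row per biallelic SNP.
#' @param samples Tibble/data frame with columns `sample_id`, `population`.
#' @param dosage Integer matrix, samples x SNPs, counting copies of the
#'   alternative allele; `NA` encodes a missing genotype.
#' @return An object of class `geno_matrix`.
#' @export
genotype_matrix <- function(snps, samples, dosage) {
  snps <- validate_snp_table(snps)
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "population") %in% names(samples))) {
    abort("`samples` needs columns sample_id and population")
  }
  samples$sample_id <- as.character(samples$sample_id)
  samples$population <- as.character(samples$population)
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicate sample ids in `samples`")
  }
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nrow(samples) || ncol(dosage) != nrow(snps)) {
    abort(sprintf(
      "dosage is %d x %d but there are %d samples and %d SNPs",
      nrow(dosage), ncol(dosage), nrow(samples), nrow(snps)
    ))
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  dimnames(dosage) <- list(samples$sample_id, snps$id)
  structure(
    list(snps = snps, samples = samples, dosage = dosage),
    class = "geno_matrix"
  )
}

#' Construct a pooled frequency table
#'
#' The "reference" side: per-population, per-SNP alternative-allele read counts
#' and total depths from pooled sequencing.
#'
#' @param snps SNP table as in [genotype_matrix()].
#' @param populations Tibble with columns `population`, `n_individuals`.
#' @param alt_reads,depth Integer matrices, populations x SNPs, with
#'   `alt_reads <= depth` elementwise.
#' @return An object of class `pool_table`.
#' @export
pool_table <- function(snps, populations, alt_reads, depth) {
  snps <- validate_snp_table(snps)
  populations <- as_tibble(populations)
  if (!all(c("population", "n_individuals") %in% names(populations))) {
    abort("`populations` needs columns population and n_individuals")
  }
  populations$population <- as.character(populations$population)
  if (anyDuplicated(populations$population)) {
    abort("duplicate population labels")
  }
  if (any(populations$n_individuals < 1L)) {
    abort("n_individuals must be >= 1 for every population")
  }
  alt_reads <- as.matrix(alt_reads)
  depth <- as.matrix(depth)
  storage.mode(alt_reads) <- "integer"
  storage.mode(depth) <- "integer"
  dims_ok <- all(dim(alt_reads) == c(nrow(populations), nrow(snps))) &&
    all(dim(depth) == c(nrow(populations), nrow(snps)))
  if (!dims_ok) {
    abort("alt_reads and depth must both be populations x SNPs")
  }
  if (any(alt_reads < 0L) || any(depth < 0L)) {
    abort("read counts must be nonnegative")
  }
  if (any(alt_reads > depth)) {
    abort("alt_reads exceeds depth at one or more entries")
  }
  dimnames(alt_reads) <- dimnames(depth) <-
    list(populations$population, snps$id)
  structure(
    list(snps = snps, populations = populations,
         alt_reads = alt_reads, depth = depth),
    class = "pool_table"
  )
}

#' Construct a population-by-locus allele frequency matrix
#'
#' The shared currency of the diversity statistics: alternative-allele
#' frequencies per population per locus, plus per-population sample sizes.
#'
#' @param populations Tibble with columns `population`, `n` (individuals).
#' @param freq Numeric matrix, populations x loci, values in \[0, 1\] or NA.
#' @param loci Character vector of locus ids (defaults to `colnames(freq)`).
#' @return An object of class `freq_matrix`.
#' @export
frequency_matrix <- function(populations, freq, loci = colnames(freq)) {
  populations <- as_tibble(populations)
  if (!all(c("population", "n") %in% names(populations))) {
    abort("`populations` needs columns population and n")
  }
  populations$population <- as.character(populations$population)
  freq <- as.matrix(freq)
  storage.mode(freq) <- "double"
  if (nrow(freq) != nrow(populations)) {
    abort("freq must have one row per population")
  }
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(freq)))
  loci <- as.character(loci)
  if (length(loci) != ncol(freq)) {
    abort("`loci` length must match ncol(freq)")
  }
  vals <- freq[!is.na(freq)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  if (any(populations$n < 1)) abort("population sample sizes must be >= 1")
  dimnames(freq) <- list(populations$population, loci)
  structure(
    list(populations = populations, loci = loci, freq = freq),
    class = "freq_matrix"
  )
}

validate_snp_table <- function(snps) {
  snps <- as_tibble(snps)
  needed <- c("id", "chromosome", "position", "ref_allele", "alt_allele")
  missing_cols <- setdiff(needed, names(snps))
  if (length(missing_cols)) {
    abort(paste0("SNP table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  snps <- snps[needed]
  snps$id <- as.character(snps$id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position <- as.integer(snps$position)
  snps$ref_allele <- toupper(as.character(snps$ref_allele))
  snps$alt_allele <- toupper(as.character(snps$alt_allele))
  if (anyDuplicated(snps$id)) abort("SNP ids must be unique")
  with_pos <- !is.na(snps$position)
  if (any(snps$position[with_pos] < 1L)) abort("positions must be >= 1")
  same <- with_pos & !is.na(snps$ref_allele) &
    snps$ref_allele == snps$alt_allele
  if (any(snps$ref_allele == snps$alt_allele, na.rm = TRUE)) {
    abort("ref_allele must differ from alt_allele")
  }
  snps
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs, %d populations, %.2f%% missing\n",
    nrow(x$dosage), ncol(x$dosage),
    length(unique(x$samples$population)),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
print.pool_table <- function(x, ...) {
  cat(sprintf(
    "<pool_table> %d populations x %d SNPs, mean depth %.1f\n",
    nrow(x$alt_reads), ncol(x$alt_reads), mean(x$depth)
  ))
  invisible(x)
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf(
    "<freq_matrix> %d populations x %d loci (mean n = %.1f)\n",
    nrow(x$freq), ncol(x$freq), mean(x$populations$n)
  ))
  invisible(x)
}

# Number of SNPs/loci, shared accessor.
n_loci <- function(x) {
  switch(class(x)[1],
    geno_matrix = nrow(x$snps),
    pool_table = nrow(x$snps),
    freq_matrix = length(x$loci),
    abort("unsupported type")
  )
}

# Restrict an object to a subset of locus ids (order taken from the object).
subset_loci <- function(x, ids) {
  keep <- x$snps$id %in% ids
  if (inherits(x, "geno_matrix")) {
    genotype_matrix(x$snps[keep, ], x$samples, x$dosage[, keep, drop = FALSE])
  } else if (inherits(x, "pool_table")) {
    pool_table(x$snps[keep, ], x$populations,
               x$alt_reads[, keep, drop = FALSE], x$depth[, keep, drop = FALSE])
  } else {
    abort("unsupported type for subset_loci")
  }
}
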