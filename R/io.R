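#' Read a sample-to-population map
#'
#' Two-column TSV (`sample_id`, `population`), with or without a header row.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `sample_id`, `population`.
#' @export
read_panel <- function(path) {
  stop_if_missing_file(path, "panel map")
  first <- readr::read_tsv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE, progress = FALSE)
  has_header <- identical(tolower(as.character(first[1, 1])), "sample_id")
  tab <- readr::read_tsv(
    path, col_names = if (has_header) TRUE else c("sample_id", "population"),
    skip = 0, show_col_types = FALSE, progress = FALSE
  )
  tab <- as_tibble(tab)[, 1:2]
  names(tab) <- c("sample_id", "population")
  tab$sample_id <- as.character(tab$sample_id)
  tab$population <- as.character(tab$population)
  tab
}

#' Read individual genotypes into a genotype matrix
#'
#' Accepts VCF (v4.x, biallelic SNPs only), the package's genotype TSV dialect
#' (header row of SNP ids, one row per sample, cells in \{0, 1, 2, NA\}), or
#' PLINK-style text `.ped`/`.map` pairs. Dosages count alternative-allele
#' copies; SNPs are returned sorted by (chromosome, position).
#'
#' @param path Genotype file. For `format = "ped"` this is the `.ped` file and
#'   a matching `.map` is expected alongside (or pass `map_path`).
#' @param panel Sample-to-population map: a path or a tibble as returned by
#'   [read_panel()]. Every genotyped sample must appear in the map.
#' @param format One of "auto", "vcf", "tsv", "ped".
#' @param map_path Optional `.map` path for PLINK input.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, panel, format = c("auto", "vcf", "tsv", "ped"),
                           map_path = NULL) {
  format <- match.arg(format)
  stop_if_missing_file(path, "genotype")
  if (is.character(panel)) panel <- read_panel(panel)
  panel <- as_tibble(panel)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
      else if (grepl("\\.ped$", path)) "ped"
      else "tsv"
  }
  geno <- switch(format,
    vcf = read_genotypes_vcf(path),
    tsv = read_genotypes_tsv(path),
    ped = read_genotypes_ped(path, map_path)
  )
  unknown <- setdiff(geno$samples$sample_id, panel$sample_id)
  if (length(unknown)) {
    abort(paste0("sample(s) not in the population map: ",
                 paste(unknown, collapse = ", ")),
          class = "ascbias_unknown_sample")
  }
  geno$samples$population <-
    panel$population[match(geno$samples$sample_id, panel$sample_id)]
  ord <- locus_order(geno$snps$chromosome, geno$snps$position)
  genotype_matrix(geno$snps[ord, ], geno$samples,
                  geno$dosage[, ord, drop = FALSE])
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  bad <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
    !fix$REF %in% c("A", "C", "G", "T") | !fix$ALT %in% c("A", "C", "G", "T")
  if (any(bad)) {
    abort(paste0(
      "multi-allelic or non-SNP record(s) at: ",
      paste(paste0(fix$CHROM[bad], ":", fix$POS[bad]), collapse = ", ")
    ), class = "ascbias_bad_record")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no genotype (GT) fields")
  alleles <- gsub("[|]", "/", gt)
  count_alt <- function(x) {
    parts <- strsplit(x, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (any(p == ".") || length(p) != 2L) return(NA_integer_)
      sum(p == "1")
    }, integer(1))
  }
  dos <- apply(alleles, 2, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(
    fix$CHROM[is.na(ids) | ids == "."], "_", fix$POS[is.na(ids) | ids == "."]
  )
  snps <- tibble(
    id = make.unique(ids), chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT
  )
  list(
    snps = snps,
    samples = tibble(sample_id = colnames(gt), population = NA_character_),
    dosage = t(dos)
  )
}

read_genotypes_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tab)[1] != "sample_id") {
    abort("genotype TSV must have `sample_id` as its first column")
  }
  ids <- names(tab)[-1]
  dos <- as.matrix(tab[, -1])
  storage.mode(dos) <- "integer"
  sites_path <- paste0(path, ".sites")
  if (file.exists(sites_path)) {
    sites <- readr::read_tsv(sites_path, show_col_types = FALSE,
                             progress = FALSE)
    snps <- tibble(
      id = as.character(sites$id), chromosome = as.character(sites$chromosome),
      position = as.integer(sites$position),
      ref_allele = sites$ref_allele, alt_allele = sites$alt_allele
    )
    snps <- snps[match(ids, snps$id), ]
  } else {
    # Fall back to ids of the form chrom:pos:ref:alt, else synthesise loci.
    parts <- strsplit(ids, ":", fixed = TRUE)
    parsed <- all(lengths(parts) == 4L)
    if (parsed) {
      snps <- tibble(
        id = ids,
        chromosome = vapply(parts, `[`, "", 1),
        position = as.integer(vapply(parts, `[`, "", 2)),
        ref_allele = vapply(parts, `[`, "", 3),
        alt_allele = vapply(parts, `[`, "", 4)
      )
    } else {
      snps <- tibble(
        id = ids, chromosome = "1", position = seq_along(ids),
        ref_allele = "A", alt_allele = "C"
      )
    }
  }
  list(
    snps = snps,
    samples = tibble(sample_id = as.character(tab$sample_id),
                     population = NA_character_),
    dosage = dos
  )
}

read_genotypes_ped <- function(path, map_path = NULL) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  stop_if_missing_file(map_path, "PLINK map")
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = "character")
  names(map)[1:4] <- c("chromosome", "id", "cm", "position")
  ped <- utils::read.table(path, header = FALSE, colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snp) {
    abort("ped/map column counts disagree")
  }
  allele <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- allele[, seq(1, 2 * n_snp, by = 2), drop = FALSE]
  a2 <- allele[, seq(2, 2 * n_snp, by = 2), drop = FALSE]
  snps <- vector("list", n_snp)
  dos <- matrix(NA_integer_, nrow(ped), n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    lev <- sort(unique(obs))
    if (length(lev) > 2) abort(sprintf("SNP %s has >2 alleles", map$id[j]))
    counts <- table(factor(obs, levels = lev))
    # ref = major allele (ties broken alphabetically), alt = the other.
    ref <- lev[which.max(counts)]
    alt <- if (length(lev) == 2) setdiff(lev, ref) else "N"
    dos[, j] <- ifelse(a1[, j] == "0" | a2[, j] == "0", NA_integer_,
                       (a1[, j] == alt) + (a2[, j] == alt))
    snps[[j]] <- tibble(id = map$id[j], chromosome = map$chromosome[j],
                        position = as.integer(map$position[j]),
                        ref_allele = ref, alt_allele = alt)
  }
  list(
    snps = dplyr::bind_rows(snps),
    samples = tibble(sample_id = as.character(ped[[2]]),
                     population = NA_character_),
    dosage = dos
  )
}

#' Write a genotype matrix as the package's TSV dialect
#'
#' Writes the dosage table (`sample_id` column + one column per SNP id) plus a
#' companion `<path>.sites` TSV holding the SNP metadata, so that
#' [read_genotypes()] round-trips exactly.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  tab <- as_tibble(as.data.frame(geno$dosage, check.names = FALSE))
  tab <- dplyr::bind_cols(tibble(sample_id = geno$samples$sample_id), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(geno$snps[, c("id", "chromosome", "position",
                                 "ref_allele", "alt_allele")],
                   paste0(path, ".sites"), progress = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' @param geno A [genotype_matrix()].
#' @param path Output `.vcf` path (uncompressed text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ascbias",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples$sample_id), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(n_loci(geno))) {
    d <- geno$dosage[, j]
    gts <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(
      geno$snps$chromosome[j], geno$snps$position[j], geno$snps$id[j],
      geno$snps$ref_allele[j], geno$snps$alt_allele[j], ".", "PASS", ".",
      "GT", gts
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a pooled-sequencing allele count table
#'
#' Long TSV with columns `chromosome`, `position`, `ref`, `alt`, `population`,
#' `alt_reads`, `depth`, `n_individuals`; one row per (population, locus).
#'
#' @param path Input TSV path.
#' @return A [pool_table()]. Loci are sorted by (chromosome, position).
#' @export
read_pool_table <- function(path) {
  stop_if_missing_file(path, "pool table")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("chromosome", "position", "ref", "alt", "population",
              "alt_reads", "depth", "n_individuals")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    abort(paste0("pool table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab) == 0) {
    return(pool_table(
      tibble(id = character(), chromosome = character(),
             position = integer(), ref_allele = character(),
             alt_allele = character()),
      tibble(population = character(), n_individuals = integer()),
      matrix(integer(), 0, 0), matrix(integer(), 0, 0)
    ))
  }
  bad <- which(tab$alt_reads > tab$depth)
  if (length(bad)) {
    abort(paste0("alt_reads > depth at row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  tab$chromosome <- as.character(tab$chromosome)
  key <- paste(tab$population, locus_key(tab$chromosome, tab$position))
  if (anyDuplicated(key)) {
    abort("duplicate (population, locus) rows in pool table")
  }
  loci <- dplyr::distinct(tab, .data$chromosome, .data$position,
                          .data$ref, .data$alt)
  ord <- locus_order(loci$chromosome, loci$position)
  loci <- loci[ord, ]
  lkey <- locus_key(loci$chromosome, loci$position)
  if (anyDuplicated(lkey)) {
    abort("same (chromosome, position) appears with different alleles")
  }
  pops <- dplyr::distinct(tab, .data$population, .data$n_individuals)
  if (anyDuplicated(pops$population)) {
    abort("a population appears with inconsistent n_individuals")
  }
  row_i <- match(tab$population, pops$population)
  col_j <- match(locus_key(tab$chromosome, tab$position), lkey)
  alt_m <- matrix(0L, nrow(pops), nrow(loci))
  dep_m <- matrix(0L, nrow(pops), nrow(loci))
  alt_m[cbind(row_i, col_j)] <- as.integer(tab$alt_reads)
  dep_m[cbind(row_i, col_j)] <- as.integer(tab$depth)
  snps <- tibble(
    id = paste0(loci$chromosome, "_", loci$position),
    chromosome = loci$chromosome, position = as.integer(loci$position),
    ref_allele = loci$ref, alt_allele = loci$alt
  )
  pool_table(snps, pops, alt_m, dep_m)
}

#' Write a pool table as long TSV
#'
#' @param pool A [pool_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pool_table <- function(pool, path) {
  n_pop <- nrow(pool$populations)
  n_snp <- n_loci(pool)
  tab <- tibble(
    chromosome = rep(pool$snps$chromosome, each = n_pop),
    position = rep(pool$snps$position, each = n_pop),
    ref = rep(pool$snps$ref_allele, each = n_pop),
    alt = rep(pool$snps$alt_allele, each = n_pop),
    population = rep(pool$populations$population, times = n_snp),
    alt_reads = as.vector(pool$alt_reads),
    depth = as.vector(pool$depth),
    n_individuals = rep(pool$populations$n_individuals, times = n_snp)
  )
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read / write a PHYLIP square distance matrix
#'
#' @param path File path.
#' @return `read_phylip_dist()` returns a labeled symmetric matrix.
#' @export
read_phylip_dist <- function(path) {
  stop_if_missing_file(path, "distance matrix")
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[2:(n + 1)]), "[[:space:]]+")
  labels <- vapply(parts, `[`, "", 1)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(m) <- list(labels, labels)
  m
}

#' @rdname read_phylip_dist
#' @param m Labeled symmetric matrix.
#' @export
write_phylip_dist <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i],
                       formatC(m[i, ], format = "g", digits = 10)),
                     collapse = "  "), con)
  }
  invisible(path)
}
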