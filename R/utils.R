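# Internal helpers shared across modules.

# Derive a deterministic child seed for a named stage from a root seed.
# Keeps results < 2^31 - 1 so they remain valid R integer seeds.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * (seq_along(codes) %% 31 + 1))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Chromosome names are compared as exact strings after stripping an optional
# "chr"/"Chr" prefix, so "chr1" and "1" refer to the same chromosome.
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

# Order loci by (chromosome, position); numeric-looking chromosome names sort
# numerically ("2" before "10"), the rest lexicographically after them.
locus_order <- function(chrom, pos) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, as.character(chrom), pos)
}

locus_key <- function(chrom, pos) {
  paste(normalize_chrom(chrom), pos, sep = ":")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_if_missing_file <- function(path, what = "input") {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), class = "ascbias_missing_file")
  }
  invisible(path)
}
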