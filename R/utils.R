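# internal helpers shared across modules

# canonical string for an unordered isoform pair; used as edge identity
pair_key <- function(gene_a, iso_a, gene_b, iso_b) {
  if (length(gene_a) == 0L) return(character(0))
  a <- paste0(gene_a, "\t", iso_a)
  b <- paste0(gene_b, "\t", iso_b)
  swap <- b < a
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste0(key_a, "\t", key_b)
}

# exon key string from interval components (0-based half-open)
exon_key_string <- function(chrom, start, end, strand) {
  if (length(chrom) == 0L) return(character(0))
  paste0(chrom, ":", start, "-", end, ":", strand)
}

# strands are compatible when equal or when either is unknown
strand_compatible <- function(a, b) {
  is.na(a) | is.na(b) | a == "*" | b == "*" | a == b
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    stop(sprintf("'%s' must be a single number in (0, 1)", name), call. = FALSE)
  }
}
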