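#' Read an exon-level expression table
#'
#' Reads per-sample exon expression in either of two headered TSV dialects
#' (lines starting with `#` are ignored):
#' \describe{
#'   \item{long}{columns `sample_id`, `chrom`, `start`, `end`, `strand`,
#'     `value`; one row per (exon, sample).}
#'   \item{wide}{columns `chrom`, `start`, `end`, `strand` followed by one
#'     column per sample; one row per exon.}
#' }
#' The dialect is auto-detected from the header. Coordinates are taken as
#' 0-based half-open genomic intervals.
#'
#' @param file path to the TSV file.
#' @return an object of class `exon_expression`: a list with `intervals`
#'   (data frame `chrom`, `start`, `end`, `strand`), `values` (exon-by-sample
#'   numeric matrix, `NA` = missing) and `samples` (ordered sample ids).
#' @export
read_exon_expression <- function(file) {
  if (!file.exists(file)) stop("exon expression file not found: ", file)
  tab <- read.delim(file, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  cols <- colnames(tab)
  if (all(c("sample_id", "chrom", "start", "end", "value") %in% cols)) {
    if (!"strand" %in% cols) tab$strand <- "*"
    ints <- unique(tab[, c("chrom", "start", "end", "strand")])
    rownames(ints) <- NULL
    samples <- unique(tab$sample_id)
    key <- exon_key_string(tab$chrom, tab$start, tab$end, tab$strand)
    ikey <- exon_key_string(ints$chrom, ints$start, ints$end, ints$strand)
    values <- matrix(NA_real_, nrow(ints), length(samples),
                     dimnames = list(ikey, samples))
    values[cbind(match(key, ikey), match(tab$sample_id, samples))] <- tab$value
  } else if (all(c("chrom", "start", "end") %in% cols)) {
    if (!"strand" %in% cols) tab$strand <- "*"
    meta <- c("chrom", "start", "end", "strand")
    samples <- setdiff(cols, meta)
    if (length(samples) == 0L) stop("wide exon table has no sample columns")
    ints <- tab[, meta]
    rownames(ints) <- NULL
    values <- as.matrix(tab[, samples, drop = FALSE])
    rownames(values) <- exon_key_string(ints$chrom, ints$start, ints$end,
                                        ints$strand)
  } else {
    stop("unrecognised exon expression header in ", file,
         " (need sample_id/chrom/start/end/value or chrom/start/end/samples)")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative expression values in ", file)
  }
  structure(
    list(intervals = ints, values = values, samples = colnames(values)),
    class = "exon_expression"
  )
}

#' Read an isoform expression table
#'
#' Reads a long-format headered TSV with columns `sample_id`, `isoform_id`,
#' `value` (lines starting with `#` ignored) into an isoform-by-sample
#' matrix.
#'
#' @param file path to the TSV file.
#' @return numeric matrix with isoform ids as row names and sample ids as
#'   column names; missing combinations become `NA`.
#' @export
read_isoform_expression <- function(file) {
  if (!file.exists(file)) stop("isoform expression file not found: ", file)
  tab <- read.delim(file, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("sample_id", "isoform_id", "value")
  if (!all(need %in% colnames(tab))) {
    stop("isoform expression TSV must carry columns: ",
         paste(need, collapse = ", "))
  }
  isoforms <- unique(tab$isoform_id)
  samples <- unique(tab$sample_id)
  m <- matrix(NA_real_, length(isoforms), length(samples),
              dimnames = list(isoforms, samples))
  m[cbind(match(tab$isoform_id, isoforms), match(tab$sample_id, samples))] <-
    tab$value
  if (any(m < 0, na.rm = TRUE)) stop("negative isoform expression in ", file)
  m
}

#' @export
print.exon_expression <- function(x, ...) {
  cat("Exon expression table:", nrow(x$values), "exon interval(s) x",
      length(x$samples), "sample(s)\n")
  cat("  missing values:", sum(is.na(x$values)), "\n")
  invisible(x)
}
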