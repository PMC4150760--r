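#' Retain exons expressed in a minimum fraction of samples
#'
#' An exon is "expressed" in a sample when its value is present (not `NA`)
#' and strictly positive. Exons whose expressed-sample fraction is at least
#' `min_fraction` are retained, in their original order; inference with half
#' of the data absent is not considered reliable.
#'
#' @param values exon-by-sample numeric matrix.
#' @param min_fraction fraction in (0, 1\]; default 0.5.
#' @return integer vector of retained row indices (possibly empty, with a
#'   warning).
#' @export
filter_expressed_exons <- function(values, min_fraction = 0.5) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1) {
    stop("'min_fraction' must be a single number in (0, 1]")
  }
  expressed <- !is.na(values) & values > 0
  frac <- rowMeans(expressed)
  keep <- which(frac >= min_fraction)
  if (length(keep) == 0L) {
    warning("no exon is expressed in at least ",
            round(100 * min_fraction), "% of samples")
  }
  keep
}

#' Build the corrected exon-expression matrix of one isoform
#'
#' Pipeline: match the isoform's annotated exon boundaries to expression
#' rows (within `tolerance_nt`), extract raw values, multiply each exon's
#' values by the per-sample shared-exon correction weight (relative abundance
#' of the owning isoform), then drop exons expressed in fewer than
#' `min_fraction` of samples. Any missing values remaining in retained exons
#' are set to 0 (a message reports the count).
#'
#' @param isoform an isoform model.
#' @param exon_expr an [read_exon_expression()] object.
#' @param isoform_expr isoform-by-sample matrix from
#'   [read_isoform_expression()]; columns are aligned to the exon table's
#'   samples.
#' @param shared a [shared_exon_table()], or `NULL` to skip the correction
#'   (all weights 1).
#' @param tolerance_nt boundary-matching tolerance (default 5).
#' @param min_fraction expressed-exon filter threshold (default 0.5).
#' @return an object of class `isoform_matrix` (fields `values`: p x n
#'   corrected matrix with exon keys as row names and samples as column
#'   names; `isoform_id`; `gene`), or `NULL` with a warning when no exon
#'   survives matching and filtering (the isoform is untestable).
#' @export
build_isoform_matrix <- function(isoform, exon_expr, isoform_expr,
                                 shared = NULL, tolerance_nt = 5,
                                 min_fraction = 0.5) {
  samples <- exon_expr$samples
  if (!is.null(isoform_expr)) {
    miss <- setdiff(samples, colnames(isoform_expr))
    if (length(miss) > 0L) {
      stop("samples absent from isoform expression table: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    isoform_expr <- isoform_expr[, samples, drop = FALSE]
  }
  map <- match_exon_boundaries(isoform, exon_expr, tolerance_nt)
  mapped <- which(!is.na(map))
  if (length(mapped) == 0L) {
    warning("isoform ", isoform$isoform_id, " is untestable (no mapped exon)")
    return(NULL)
  }
  raw <- exon_expr$values[map[mapped], , drop = FALSE]
  keys <- character(length(mapped))
  corrected <- raw
  for (i in seq_along(mapped)) {
    e <- mapped[i]
    if (is.null(shared)) {
      keys[i] <- exon_key_string(isoform$chrom, isoform$exons$start[e],
                                 isoform$exons$end[e], isoform$strand)
      next
    }
    hit <- shared$instances$isoform_id == isoform$isoform_id &
      shared$instances$exon_index == e
    if (!any(hit)) {
      stop("isoform ", isoform$isoform_id, " exon ", e,
           " not present in the shared-exon table; rebuild the table from ",
           "the same models")
    }
    keys[i] <- shared$instances$key[hit][1L]
    cw <- correction_weights(isoform$isoform_id, keys[i], shared, isoform_expr)
    corrected[i, ] <- raw[i, ] * cw$w
    corrected[i, cw$missing] <- NA_real_
  }
  rownames(corrected) <- keys
  keep <- withCallingHandlers(
    filter_expressed_exons(corrected, min_fraction),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (length(keep) == 0L) {
    warning("isoform ", isoform$isoform_id,
            " is untestable (no exon expressed in at least ",
            round(100 * min_fraction), "% of samples)")
    return(NULL)
  }
  corrected <- corrected[keep, , drop = FALSE]
  n_zeroed <- sum(is.na(corrected))
  if (n_zeroed > 0L) {
    message("isoform ", isoform$isoform_id, ": ", n_zeroed,
            " missing value(s) in retained exons set to 0")
    corrected[is.na(corrected)] <- 0
  }
  structure(
    list(
      values = corrected,
      isoform_id = isoform$isoform_id,
      gene = isoform$gene,
      exon_keys = rownames(corrected),
      sample_ids = colnames(corrected),
      n_missing_zeroed = n_zeroed,
      unmapped_exons = which(is.na(map))
    ),
    class = "isoform_matrix"
  )
}

#' Build corrected exon-expression matrices for a set of isoforms
#'
#' Applies [build_isoform_matrix()] to every isoform model, building the
#' shared-exon table from the models when none is supplied. Untestable
#' isoforms (no mappable exon, or no exon passing the expressed filter) are
#' dropped with a warning.
#'
#' @inheritParams build_isoform_matrix
#' @param models an `isoform_models` object.
#' @return named list of `isoform_matrix` objects (names = isoform ids).
#' @export
build_isoform_matrices <- function(models, exon_expr, isoform_expr,
                                   shared = NULL, tolerance_nt = 5,
                                   min_fraction = 0.5) {
  if (is.null(shared)) shared <- shared_exon_table(models, tolerance_nt)
  out <- lapply(models, build_isoform_matrix,
                exon_expr = exon_expr, isoform_expr = isoform_expr,
                shared = shared, tolerance_nt = tolerance_nt,
                min_fraction = min_fraction)
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.isoform_matrix <- function(x, ...) {
  cat("Isoform exon-expression matrix: ", x$isoform_id,
      " (gene ", x$gene, ")\n", sep = "")
  cat("  ", nrow(x$values), " exon(s) x ", ncol(x$values), " sample(s)\n",
      sep = "")
  invisible(x)
}

#' Serialize isoform matrices to a long-format TSV
#'
#' @param matrices named list of `isoform_matrix` objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_isoform_matrices <- function(matrices, file) {
  rows <- lapply(matrices, function(m) {
    data.frame(
      gene = m$gene, isoform_id = m$isoform_id,
      exon_key = rep(rownames(m$values), ncol(m$values)),
      sample_id = rep(colnames(m$values), each = nrow(m$values)),
      value = as.vector(m$values),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  writeLines("# corrected isoform exon-expression matrices", file)
  suppressWarnings(write.table(out, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(file)
}

#' Read isoform matrices written by [write_isoform_matrices()]
#'
#' @param file path to the TSV file.
#' @return named list of `isoform_matrix` objects.
#' @export
read_isoform_matrices <- function(file) {
  tab <- read.delim(file, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("gene", "isoform_id", "exon_key", "sample_id", "value")
  if (!all(need %in% colnames(tab))) {
    stop("not an isoform-matrix TSV: ", file)
  }
  out <- lapply(split(tab, tab$isoform_id), function(d) {
    keys <- unique(d$exon_key)
    samples <- unique(d$sample_id)
    v <- matrix(NA_real_, length(keys), length(samples),
                dimnames = list(keys, samples))
    v[cbind(match(d$exon_key, keys), match(d$sample_id, samples))] <- d$value
    structure(
      list(values = v, isoform_id = d$isoform_id[1L], gene = d$gene[1L],
           exon_keys = keys, sample_ids = samples,
           n_missing_zeroed = 0L, unmapped_exons = integer(0)),
      class = "isoform_matrix"
    )
  })
  out[order(vapply(out, function(m) paste(m$gene, m$isoform_id), character(1)))]
}
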