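#' Tabulate exons shared across isoforms
#'
#' Scans a set of isoform models for shared exon boundaries. Two exons from
#' different isoforms are assigned the same canonical key when they lie on
#' the same chromosome, their strands are compatible (equal, or either
#' unknown), and both the start and the end offsets are at most
#' `tolerance_nt`. The canonical key takes the boundaries of the first-seen
#' instance, so keys are reproducible for a fixed input order.
#'
#' @param models an `isoform_models` object (or list of isoform models).
#' @param tolerance_nt non-negative integer; boundary tolerance in
#'   nucleotides (default 5).
#' @return an object of class `shared_exon_table`: a list with `keys`
#'   (data frame `key`, `chrom`, `start`, `end`, `strand`) and `instances`
#'   (data frame `key`, `gene`, `isoform_id`, `exon_index`).
#' @seealso [correction_weights()], [build_isoform_matrices()]
#' @export
shared_exon_table <- function(models, tolerance_nt = 5) {
  if (tolerance_nt < 0) stop("'tolerance_nt' must be >= 0")
  k_chrom <- character(0)
  k_start <- numeric(0)
  k_end <- numeric(0)
  k_strand <- character(0)
  inst <- vector("list", length(models))
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    p <- nrow(m$exons)
    keys_i <- integer(p)
    for (e in seq_len(p)) {
      s <- m$exons$start[e]
      en <- m$exons$end[e]
      hit <- which(
        k_chrom == m$chrom &
          strand_compatible(k_strand, m$strand) &
          abs(k_start - s) <= tolerance_nt &
          abs(k_end - en) <= tolerance_nt
      )
      if (length(hit) > 0L) {
        keys_i[e] <- hit[1L]
      } else {
        k_chrom <- c(k_chrom, m$chrom)
        k_start <- c(k_start, s)
        k_end <- c(k_end, en)
        k_strand <- c(k_strand, m$strand)
        keys_i[e] <- length(k_chrom)
      }
    }
    inst[[mi]] <- data.frame(
      key_idx = keys_i, gene = m$gene, isoform_id = m$isoform_id,
      exon_index = seq_len(p), stringsAsFactors = FALSE
    )
  }
  key_str <- exon_key_string(k_chrom, k_start, k_end, k_strand)
  instances <- do.call(rbind, inst)
  if (is.null(instances)) {
    instances <- data.frame(key = character(0), gene = character(0),
                            isoform_id = character(0), exon_index = integer(0))
  } else {
    instances$key <- key_str[instances$key_idx]
    instances$key_idx <- NULL
    instances <- instances[, c("key", "gene", "isoform_id", "exon_index")]
  }
  structure(
    list(
      keys = data.frame(key = key_str, chrom = k_chrom, start = k_start,
                        end = k_end, strand = k_strand,
                        stringsAsFactors = FALSE),
      instances = instances,
      tolerance_nt = tolerance_nt
    ),
    class = "shared_exon_table"
  )
}

#' @export
print.shared_exon_table <- function(x, ...) {
  n_inst <- table(x$instances$key)
  cat("Shared-exon table:", nrow(x$keys), "canonical exon(s),",
      sum(n_inst > 1L), "shared by >1 isoform",
      sprintf("(tolerance %d nt)\n", x$tolerance_nt))
  invisible(x)
}

#' Export a shared-exon table to TSV
#'
#' Writes one row per canonical exon with its isoform instances as a
#' semicolon-separated `gene:isoform` list.
#'
#' @param x a `shared_exon_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_shared_exons <- function(x, file) {
  inst <- split(paste0(x$instances$gene, ":", x$instances$isoform_id),
                x$instances$key)
  out <- x$keys
  out$instances <- vapply(out$key, function(k) {
    paste(inst[[k]], collapse = ";")
  }, character(1))
  writeLines(sprintf("# shared-exon table, tolerance_nt=%d", x$tolerance_nt),
             file)
  suppressWarnings(write.table(out, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(file)
}

#' Match annotated exon boundaries to expression-table intervals
#'
#' Maps each exon of one isoform to at most one row of an exon expression
#' table. A row qualifies when it lies on the same chromosome, strands are
#' compatible, and both boundary offsets are at most `tolerance_nt`. Among
#' several qualifying rows the one with the smallest total offset
#' `|dstart| + |dend|` wins; ties go to the smaller row start.
#'
#' @param isoform an isoform model (element of `isoform_models`).
#' @param intervals an `exon_expression` object or a data frame with columns
#'   `chrom`, `start`, `end`, `strand`.
#' @param tolerance_nt non-negative boundary tolerance in nucleotides
#'   (default 5).
#' @return integer vector with one entry per annotated exon: the matched row
#'   index, or `NA` for unmapped exons. A fully unmapped isoform raises a
#'   warning.
#' @export
match_exon_boundaries <- function(isoform, intervals, tolerance_nt = 5) {
  if (tolerance_nt < 0) stop("'tolerance_nt' must be >= 0")
  if (inherits(intervals, "exon_expression")) intervals <- intervals$intervals
  p <- nrow(isoform$exons)
  out <- rep(NA_integer_, p)
  for (e in seq_len(p)) {
    ds <- abs(intervals$start - isoform$exons$start[e])
    de <- abs(intervals$end - isoform$exons$end[e])
    ok <- intervals$chrom == isoform$chrom &
      strand_compatible(intervals$strand, isoform$strand) &
      ds <= tolerance_nt & de <= tolerance_nt
    if (any(ok)) {
      cand <- which(ok)
      tot <- ds[cand] + de[cand]
      cand <- cand[order(tot, intervals$start[cand])]
      out[e] <- cand[1L]
    }
  }
  if (all(is.na(out))) {
    warning("isoform ", isoform$isoform_id,
            ": no exon matched any expression row")
  }
  out
}

#' Shared-exon correction weights for one isoform
#'
#' For a canonical exon shared by `K` isoforms, the expression of each
#' instance is weighted by the relative abundance of its owning isoform:
#' `W = I_m / sum_i I_i` per sample, where `I_m` is the isoform's expression.
#' An unshared exon (`K = 1`) has weight 1 in every sample. When the total
#' abundance in a sample is zero the relative abundance is undefined; the
#' weight is returned as 0 and the sample is flagged missing.
#'
#' @param isoform_id isoform owning the instance.
#' @param exon_key canonical exon key (a `key` value of the shared table).
#' @param shared a [shared_exon_table()].
#' @param isoform_expr isoform-by-sample expression matrix (rows named by
#'   isoform id); every isoform sharing the exon must be present.
#' @return list with `w` (named weight vector over samples, in \[0, 1\]) and
#'   `missing` (logical vector flagging zero-denominator samples).
#' @export
correction_weights <- function(isoform_id, exon_key, shared, isoform_expr) {
  inst <- shared$instances[shared$instances$key == exon_key, , drop = FALSE]
  if (nrow(inst) == 0L) stop("exon key not present in shared table: ", exon_key)
  sharing <- unique(inst$isoform_id)
  if (!isoform_id %in% sharing) {
    stop("isoform ", isoform_id, " does not carry exon ", exon_key)
  }
  samples <- colnames(isoform_expr)
  nsamp <- ncol(isoform_expr)
  if (length(sharing) == 1L) {
    w <- rep(1, nsamp)
    names(w) <- samples
    return(list(w = w, missing = rep(FALSE, nsamp)))
  }
  absent <- setdiff(sharing, rownames(isoform_expr))
  if (length(absent) > 0L) {
    stop("isoform(s) absent from isoform expression table: ",
         paste(absent, collapse = ", "))
  }
  abund <- isoform_expr[sharing, , drop = FALSE]
  abund[is.na(abund)] <- 0
  denom <- colSums(abund)
  w <- ifelse(denom > 0, abund[isoform_id, ] / denom, 0)
  names(w) <- samples
  list(w = w, missing = denom <= 0)
}
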