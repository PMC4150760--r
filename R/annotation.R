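#' Read transcript annotation for a set of genes
#'
#' Parses a transcript annotation file and returns one exon model per isoform
#' of each requested gene. Two dialects are supported: GTF (1-based inclusive
#' coordinates, `exon` features grouped by `transcript_id` / `gene_name`) and
#' refFlat-like TSV (columns `geneName`, `name`, `chrom`, `strand`,
#' `exonStarts`, `exonEnds`, the last two comma-separated lists in 0-based
#' half-open coordinates). All coordinates are normalised to the internal
#' 0-based half-open convention.
#'
#' @param file path to the annotation file.
#' @param genes character vector of gene symbols to retain; must be non-empty.
#' @param format `"auto"` (by extension), `"gtf"` or `"refflat"`.
#' @return an object of class `isoform_models`: a list of isoform models,
#'   ordered by (gene, isoform id). Each element carries `isoform_id`,
#'   `gene`, `chrom`, `strand` and an `exons` data frame (`start`, `end`),
#'   sorted by start and pairwise non-overlapping.
#' @seealso [shared_exon_table()], [build_isoform_matrices()]
#' @export
read_annotation <- function(file, genes, format = c("auto", "gtf", "refflat")) {
  format <- match.arg(format)
  if (!is.character(genes) || length(genes) == 0L) {
    stop("'genes' must be a non-empty character vector of gene symbols")
  }
  if (!file.exists(file)) stop("annotation file not found: ", file)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", file, ignore.case = TRUE)) {
      "gtf"
    } else {
      "refflat"
    }
  }
  models <- switch(format,
    gtf = parse_gtf(file),
    refflat = parse_refflat(file)
  )
  keep <- vapply(models, function(m) m$gene %in% genes, logical(1))
  models <- models[keep]
  found <- unique(vapply(models, function(m) m$gene, character(1)))
  missing <- setdiff(genes, found)
  if (length(missing) > 0L) {
    warning("no isoforms found for gene(s): ", paste(missing, collapse = ", "))
  }
  ord <- order(
    vapply(models, function(m) m$gene, character(1)),
    vapply(models, function(m) m$isoform_id, character(1))
  )
  models <- models[ord]
  names(models) <- vapply(models, function(m) m$isoform_id, character(1))
  structure(models, class = "isoform_models")
}

new_isoform_model <- function(isoform_id, gene, chrom, strand, starts, ends) {
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  if (any(starts >= ends)) {
    stop("isoform ", isoform_id, ": exon with start >= end")
  }
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)])) {
    stop("isoform ", isoform_id, ": overlapping exons within one isoform")
  }
  structure(
    list(
      isoform_id = isoform_id, gene = gene, chrom = chrom,
      strand = strand,
      exons = data.frame(start = starts, end = ends)
    ),
    class = "isoform_model"
  )
}

parse_gtf <- function(file) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the 'rtracklayer' package; ",
         "alternatively supply a refFlat-like TSV")
  }
  gr <- as.data.frame(rtracklayer::import(file, format = "gtf"))
  gr <- gr[gr$type == "exon", , drop = FALSE]
  if (nrow(gr) == 0L) stop("no exon features found in GTF: ", file)
  tx <- as.character(gr$transcript_id)
  gene <- if ("gene_name" %in% colnames(gr) && !all(is.na(gr$gene_name))) {
    as.character(gr$gene_name)
  } else {
    as.character(gr$gene_id)
  }
  if (any(is.na(tx))) stop("GTF exon feature without transcript_id")
  # GTF is 1-based inclusive; convert to 0-based half-open
  start0 <- gr$start - 1L
  end0 <- gr$end
  chrom <- as.character(gr$seqnames)
  strand <- as.character(gr$strand)
  lapply(split(seq_len(nrow(gr)), tx), function(idx) {
    new_isoform_model(
      isoform_id = tx[idx[1L]], gene = gene[idx[1L]],
      chrom = chrom[idx[1L]], strand = strand[idx[1L]],
      starts = start0[idx], ends = end0[idx]
    )
  })
}

parse_refflat <- function(file) {
  first <- readLines(file, n = 50L)
  first <- first[!startsWith(first, "#")]
  if (length(first) == 0L) stop("empty annotation file: ", file)
  has_header <- grepl("geneName", first[1L], fixed = TRUE)
  tab <- read.delim(file, header = has_header, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(tab) < 6L) stop("unknown annotation dialect in ", file)
    colnames(tab)[1:6] <- c("geneName", "name", "chrom", "strand",
                            "exonStarts", "exonEnds")
  }
  need <- c("geneName", "name", "chrom", "strand", "exonStarts", "exonEnds")
  if (!all(need %in% colnames(tab))) {
    stop("annotation TSV must carry columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    starts <- as.numeric(strsplit(tab$exonStarts[i], ",")[[1L]])
    ends <- as.numeric(strsplit(tab$exonEnds[i], ",")[[1L]])
    if (length(starts) != length(ends)) {
      stop("row ", i, ": exonStarts/exonEnds length mismatch")
    }
    new_isoform_model(
      isoform_id = tab$name[i], gene = tab$geneName[i],
      chrom = tab$chrom[i], strand = tab$strand[i],
      starts = starts, ends = ends
    )
  })
}

#' @export
print.isoform_models <- function(x, ...) {
  genes <- vapply(x, function(m) m$gene, character(1))
  cat("Isoform models:", length(x), "isoform(s) across",
      length(unique(genes)), "gene(s)\n")
  for (g in unique(genes)) {
    ids <- names(x)[genes == g]
    cat("  ", g, ": ", paste(ids, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
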