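#' Write a co-expression network to disk
#'
#' The TSV format stores one row per tested pair with columns `gene_a`,
#' `isoform_a`, `gene_b`, `isoform_b`, `p`, `q`, `n`, `L_n`, `statistic`,
#' `p_value`, `edge`; provenance (condition, alpha, sample count) is carried
#' in `#`-prefixed header lines so the file round-trips through
#' [read_network()]. GraphML output (via igraph) keeps the significant edges
#' with their attributes.
#'
#' @param x an `ldtnet` object.
#' @param file output path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return `file`, invisibly.
#' @export
write_network <- function(x, file, format = c("tsv", "graphml")) {
  stopifnot(inherits(x, "ldtnet"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(x), file, format = "graphml")
    return(invisible(file))
  }
  hdr <- c(
    "# ldtnet co-expression network",
    sprintf("# condition=%s", x$condition),
    sprintf("# alpha=%g", x$alpha),
    sprintf("# n_samples=%d", x$n_samples),
    sprintf("# include_intragene=%s", x$include_intragene),
    sprintf("# p_adjust_method=%s", x$p_adjust_method)
  )
  writeLines(hdr, file)
  suppressWarnings(write.table(x$tests, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(file)
}

#' Read a network written by [write_network()]
#'
#' @param file path to a network TSV.
#' @return an `ldtnet` object (the `skipped` table is not persisted and
#'   comes back empty).
#' @export
read_network <- function(file) {
  if (!file.exists(file)) stop("network file not found: ", file)
  hdr <- grep("^#", readLines(file, n = 20L), value = TRUE)
  get_field <- function(name, default = NA_character_) {
    hit <- grep(paste0("^# ", name, "="), hdr, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(paste0("^# ", name, "="), "", hit[1L])
  }
  tests <- read.delim(file, header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
  need <- c("gene_a", "isoform_a", "gene_b", "isoform_b", "p_value", "edge")
  if (!all(need %in% colnames(tests))) {
    stop("not an ldtnet network TSV: ", file)
  }
  tests$edge <- as.logical(tests$edge)
  nodes <- unique(rbind(
    data.frame(gene = tests$gene_a, isoform_id = tests$isoform_a,
               stringsAsFactors = FALSE),
    data.frame(gene = tests$gene_b, isoform_id = tests$isoform_b,
               stringsAsFactors = FALSE)
  ))
  nodes <- nodes[order(nodes$gene, nodes$isoform_id), , drop = FALSE]
  rownames(nodes) <- NULL
  cond <- get_field("condition")
  if (identical(cond, "NA")) cond <- NA_character_
  structure(
    list(
      nodes = nodes, tests = tests,
      skipped = data.frame(gene_a = character(0), isoform_a = character(0),
                           gene_b = character(0), isoform_b = character(0),
                           reason = character(0)),
      alpha = as.numeric(get_field("alpha", "0.05")),
      include_intragene = as.logical(get_field("include_intragene", "FALSE")),
      p_adjust_method = get_field("p_adjust_method", "none"),
      condition = cond,
      n_samples = as.integer(get_field("n_samples", "0")),
      call = NULL
    ),
    class = "ldtnet"
  )
}

#' Write a differential network to TSV
#'
#' One row per differential or common edge with a `status` column in
#' `{lost, gained, common}` and a `note` column flagging edges untestable in
#' the opposite condition.
#'
#' @param x an `ldtnet_diff` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_diff_network <- function(x, file) {
  stopifnot(inherits(x, "ldtnet_diff"))
  blocks <- list(
    if (nrow(x$lost)) cbind(x$lost, status = "lost"),
    if (nrow(x$gained)) cbind(x$gained, status = "gained"),
    if (nrow(x$common)) cbind(x$common, status = "common")
  )
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  out <- if (length(blocks)) {
    do.call(rbind, blocks)
  } else {
    cbind(empty_tests_df(), weight = numeric(0), note = character(0),
          status = character(0))
  }
  hdr <- c(
    "# ldtnet differential network",
    sprintf("# condition_a=%s", x$condition_a),
    sprintf("# condition_b=%s", x$condition_b),
    sprintf("# alpha=%g", x$alpha)
  )
  writeLines(hdr, file)
  suppressWarnings(write.table(out, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(file)
}

#' Write simulation results to TSV
#'
#' @param x an `ldt_sim` object or `ldt_sim_table` data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sim_table <- function(x, file) {
  if (inherits(x, "ldt_sim")) x <- as.data.frame(x)
  writeLines("# ldtnet simulation results", file)
  suppressWarnings(write.table(x, file, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(file)
}
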