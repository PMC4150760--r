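# Shared helpers: in-code fixtures, cached across tests within one run.

# one fixture set per session, generated lazily
fixture_cache <- local({
  env <- new.env()
  function(seed = 42, n_samples = 100) {
    key <- paste0("fx_", seed, "_", n_samples)
    if (is.null(env[[key]])) {
      dir <- file.path(tempdir(), key)
      env[[key]] <- suppressMessages(
        generate_fixtures(dir, seed = seed, n_samples = n_samples)
      )
    }
    env[[key]]
  }
})

# two isoforms of one gene sharing exon 1, plus a second gene, as plain
# in-memory objects; used by the matrix-construction tests
toy_models <- function() {
  structure(
    list(
      ISO1 = new_toy_model("ISO1", "GA", "chr1",
                           starts = c(100, 500, 900),
                           ends = c(200, 600, 1000)),
      ISO2 = new_toy_model("ISO2", "GA", "chr1",
                           starts = c(100, 2500),
                           ends = c(200, 2600)),
      ISO3 = new_toy_model("ISO3", "GB", "chr2",
                           starts = c(100, 500),
                           ends = c(200, 600))
    ),
    class = "isoform_models"
  )
}

new_toy_model <- function(id, gene, chrom, starts, ends, strand = "+") {
  structure(
    list(isoform_id = id, gene = gene, chrom = chrom, strand = strand,
         exons = data.frame(start = starts, end = ends)),
    class = "isoform_model"
  )
}

# exon_expression object built directly from an interval df + value matrix
toy_exon_expression <- function(intervals, values) {
  colnames(values) <- colnames(values) %||% paste0("S", seq_len(ncol(values)))
  rownames(values) <- paste0(intervals$chrom, ":", intervals$start, "-",
                             intervals$end, ":", intervals$strand)
  structure(
    list(intervals = intervals, values = values, samples = colnames(values)),
    class = "exon_expression"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# minimal network TSV -> ldtnet, for edge-set algebra tests; edge_pairs is a
# data frame with columns isoform_a, isoform_b (genes derived as "G<iso>")
make_net <- function(edge_pairs, non_edges = NULL, alpha = 0.05,
                     condition = "normal") {
  all_pairs <- rbind(edge_pairs,
                     if (!is.null(non_edges)) non_edges)
  tests <- data.frame(
    gene_a = sub("\\..*$", "", all_pairs$isoform_a),
    isoform_a = all_pairs$isoform_a,
    gene_b = sub("\\..*$", "", all_pairs$isoform_b),
    isoform_b = all_pairs$isoform_b,
    p = 5L, q = 5L, n = 100L,
    L_n = 1, statistic = 3, p_value = all_pairs$p_value %||% 0.001,
    edge = c(rep(TRUE, nrow(edge_pairs)),
             rep(FALSE, if (is.null(non_edges)) 0L else nrow(non_edges))),
    stringsAsFactors = FALSE
  )
  if (!is.null(all_pairs$p_value)) tests$p_value <- all_pairs$p_value
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# ldtnet co-expression network",
               sprintf("# condition=%s", condition),
               sprintf("# alpha=%g", alpha),
               "# n_samples=100",
               "# include_intragene=FALSE",
               "# p_adjust_method=none"), f)
  suppressWarnings(write.table(tests, f, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  read_network(f)
}
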