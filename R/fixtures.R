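#' Generate a synthetic exon-level RNA-Seq dataset with planted networks
#'
#' Writes a complete, self-consistent input set — transcript annotation
#' (refFlat-like TSV), per-condition exon expression (long TSV) and isoform
#' expression (long TSV), plus a gene list — for a matched normal/disease
#' design with known ground truth, and returns a manifest sufficient to
#' recompute every value.
#'
#' The layout mirrors a two-gene worked example plus background genes:
#' `GENE1` has two isoforms, `GENE2` three, and each extra gene two. Within
#' each gene all isoforms share their first exon (exercising the relative-
#' abundance correction); the remaining exons are isoform-specific.
#' Co-expression is planted per condition on fixed isoform pairs
#' (normal: 1.1-2.1, 1.1-2.3, 1.2-2.3; disease: 1.1-2.1, 1.1-2.2, 1.2-2.3,
#' i.e. one edge lost and one gained in disease) by adding `c0` times the
#' partner's latent exon profile, so the per-exon cross-correlation matches
#' the dependent-pair simulation model. Exon values are
#' `baseline + noise_sd * latent` (truncated at 0.01 to stay positive);
#' isoform abundances are gamma distributed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the file set is a deterministic function of the
#'   seed and parameters.
#' @param n_samples samples per condition (default 100).
#' @param c0 planted dependence strength (default 0.6).
#' @param n_extra_genes background genes without planted edges (default 3).
#' @param unique_exons isoform-specific exons per isoform (default 4; total
#'   exons per isoform is `unique_exons + 1` counting the shared one).
#' @param baseline,noise_sd location and scale mapping latent normals to
#'   expression units (defaults 10 and 2).
#' @param abundance_shape,abundance_scale gamma parameters of the isoform
#'   abundances (defaults 5 and 2).
#' @return an object of class `fixture_manifest`: generator parameters,
#'   file paths, planted edges per condition, isoform models, and per-
#'   condition ground truth (raw exon tables, isoform abundances) from which
#'   corrected expressions are recomputable.
#' @export
generate_fixtures <- function(dir, seed = 1, n_samples = 100, c0 = 0.6,
                              n_extra_genes = 3, unique_exons = 4,
                              baseline = 10, noise_sd = 2,
                              abundance_shape = 5, abundance_scale = 2) {
  if (n_samples < 10L) stop("'n_samples' must be >= 10")
  if (n_extra_genes < 0L) stop("'n_extra_genes' must be >= 0")
  if (unique_exons < 1L) stop("'unique_exons' must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  set.seed(seed)

  iso_per_gene <- c(GENE1 = 2L, GENE2 = 3L)
  if (n_extra_genes > 0L) {
    extra <- rep(2L, n_extra_genes)
    names(extra) <- paste0("GENE", 2L + seq_len(n_extra_genes))
    iso_per_gene <- c(iso_per_gene, extra)
  }
  genes <- names(iso_per_gene)

  # isoform models: shared first exon per gene + unique downstream exons
  models <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    chrom <- paste0("chr", gi)
    for (k in seq_len(iso_per_gene[[gi]])) {
      iso <- paste0(g, ".iso", k)
      starts <- c(1000, 2000 + (k - 1) * 100000 +
                    (seq_len(unique_exons) - 1) * 1000)
      ends <- starts + 200
      models[[iso]] <- new_isoform_model(iso, g, chrom, "+", starts, ends)
    }
  }
  models <- structure(models, class = "isoform_models")

  planted <- list(
    normal = data.frame(
      child = c("GENE1.iso1", "GENE1.iso1", "GENE1.iso2"),
      parent = c("GENE2.iso1", "GENE2.iso3", "GENE2.iso3"),
      stringsAsFactors = FALSE
    ),
    disease = data.frame(
      child = c("GENE1.iso1", "GENE1.iso1", "GENE1.iso2"),
      parent = c("GENE2.iso1", "GENE2.iso2", "GENE2.iso3"),
      stringsAsFactors = FALSE
    )
  )

  conditions <- c("normal", "disease")
  sample_ids <- list(
    normal = sprintf("N%03d", seq_len(n_samples)),
    disease = sprintf("T%03d", seq_len(n_samples))
  )
  isoforms <- names(models)

  raw_exon <- list()
  abundances <- list()
  for (cond in conditions) {
    # base latents for the unique exons of every isoform
    z <- lapply(isoforms, function(iso) {
      matrix(rnorm(unique_exons * n_samples), unique_exons, n_samples)
    })
    names(z) <- isoforms
    lat <- z
    pl <- planted[[cond]]
    for (i in seq_len(nrow(pl))) {
      lat[[pl$child[i]]] <- lat[[pl$child[i]]] + c0 * z[[pl$parent[i]]]
    }
    # raw exon table: unique exons from latents, shared exons independent
    ints <- list()
    vals <- list()
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      chrom <- paste0("chr", gi)
      ints[[length(ints) + 1L]] <- data.frame(
        chrom = chrom, start = 1000, end = 1200, strand = "+",
        stringsAsFactors = FALSE
      )
      vals[[length(vals) + 1L]] <-
        pmax(baseline + noise_sd * rnorm(n_samples), 0.01)
      for (k in seq_len(iso_per_gene[[gi]])) {
        iso <- paste0(g, ".iso", k)
        ex <- models[[iso]]$exons
        for (e in seq(2L, nrow(ex))) {
          ints[[length(ints) + 1L]] <- data.frame(
            chrom = chrom, start = ex$start[e], end = ex$end[e],
            strand = "+", stringsAsFactors = FALSE
          )
          vals[[length(vals) + 1L]] <-
            pmax(baseline + noise_sd * lat[[iso]][e - 1L, ], 0.01)
        }
      }
    }
    intervals <- do.call(rbind, ints)
    values <- do.call(rbind, vals)
    values <- round(values, 4)
    colnames(values) <- sample_ids[[cond]]
    rownames(values) <- exon_key_string(intervals$chrom, intervals$start,
                                        intervals$end, intervals$strand)
    raw_exon[[cond]] <- list(intervals = intervals, values = values)
    ab <- matrix(
      round(rgamma(length(isoforms) * n_samples, shape = abundance_shape,
                   scale = abundance_scale), 4),
      length(isoforms), n_samples,
      dimnames = list(isoforms, sample_ids[[cond]])
    )
    abundances[[cond]] <- ab
  }

  # ---- write files ----
  files <- list(annotation = file.path(dir, "annotation.tsv"),
                genes = file.path(dir, "genes.txt"),
                manifest = file.path(dir, "manifest.json"))
  ann <- data.frame(
    geneName = vapply(models, function(m) m$gene, character(1)),
    name = vapply(models, function(m) m$isoform_id, character(1)),
    chrom = vapply(models, function(m) m$chrom, character(1)),
    strand = vapply(models, function(m) m$strand, character(1)),
    exonStarts = vapply(models, function(m) {
      paste(m$exons$start, collapse = ",")
    }, character(1)),
    exonEnds = vapply(models, function(m) {
      paste(m$exons$end, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  suppressWarnings(write.table(ann, files$annotation, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  writeLines(genes, files$genes)
  for (cond in conditions) {
    re <- raw_exon[[cond]]
    long <- data.frame(
      sample_id = rep(colnames(re$values), each = nrow(re$values)),
      chrom = rep(re$intervals$chrom, ncol(re$values)),
      start = rep(re$intervals$start, ncol(re$values)),
      end = rep(re$intervals$end, ncol(re$values)),
      strand = rep(re$intervals$strand, ncol(re$values)),
      value = as.vector(re$values),
      stringsAsFactors = FALSE
    )
    f_ex <- file.path(dir, paste0("exon_expr_", cond, ".tsv"))
    writeLines(sprintf("# synthetic exon expression, condition=%s, seed=%d",
                       cond, seed), f_ex)
    suppressWarnings(write.table(long, f_ex, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    files[[paste0("exon_expr_", cond)]] <- f_ex

    ab <- abundances[[cond]]
    long_iso <- data.frame(
      sample_id = rep(colnames(ab), each = nrow(ab)),
      isoform_id = rep(rownames(ab), ncol(ab)),
      value = as.vector(ab),
      stringsAsFactors = FALSE
    )
    f_iso <- file.path(dir, paste0("isoform_expr_", cond, ".tsv"))
    writeLines(sprintf("# synthetic isoform expression, condition=%s, seed=%d",
                       cond, seed), f_iso)
    suppressWarnings(write.table(long_iso, f_iso, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    files[[paste0("isoform_expr_", cond)]] <- f_iso
  }

  params <- list(seed = seed, n_samples = n_samples, c0 = c0,
                 n_extra_genes = n_extra_genes, unique_exons = unique_exons,
                 baseline = baseline, noise_sd = noise_sd,
                 abundance_shape = abundance_shape,
                 abundance_scale = abundance_scale)
  jsonlite::write_json(
    list(params = params, planted = planted,
         files = lapply(files, basename), genes = genes),
    files$manifest, auto_unbox = TRUE, pretty = TRUE
  )

  structure(
    list(params = params, files = files, genes = genes, models = models,
         planted = planted, sample_ids = sample_ids,
         raw_exon = raw_exon, abundances = abundances),
    class = "fixture_manifest"
  )
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat("Synthetic fixture set (seed ", x$params$seed, ")\n", sep = "")
  cat("  genes: ", length(x$genes), "; isoforms: ", length(x$models),
      "; samples/condition: ", x$params$n_samples, "\n", sep = "")
  cat("  planted edges: normal ", nrow(x$planted$normal), ", disease ",
      nrow(x$planted$disease), " (c0 = ", x$params$c0, ")\n", sep = "")
  cat("  files in:", dirname(x$files$annotation), "\n")
  invisible(x)
}
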