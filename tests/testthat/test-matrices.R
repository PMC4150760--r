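test_that("the expressed-exon filter keeps exons at or above the fraction", {
  v <- rbind(
    c(1, 2, 3, 4, 5, 0, 0, 0, 0, 0),        # 5/10 expressed -> kept
    c(1, 2, 3, 4, 0, 0, 0, 0, 0, 0),        # 4/10 -> dropped
    rep(NA_real_, 10),                      # all missing -> dropped
    rep(1, 10)                              # fully expressed -> kept
  )
  expect_equal(filter_expressed_exons(v, 0.5), c(1L, 4L))
  expect_warning(filter_expressed_exons(v[3, , drop = FALSE]), "50%")
  expect_error(filter_expressed_exons(v, 0), "min_fraction")
})

test_that("lowering the filter fraction never drops a retained exon", {
  set.seed(5)
  for (rep in 1:20) {
    v <- matrix(rbinom(8 * 12, 1, 0.5) * runif(8 * 12), 8, 12)
    prev <- integer(0)
    for (f in c(0.9, 0.7, 0.5, 0.3, 0.1)) {
      cur <- suppressWarnings(filter_expressed_exons(v, f))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("a shared exon's expression splits by relative isoform abundance", {
  # two isoforms of one gene share their first exon; raw value 10 with
  # abundances 3:1 yields corrected values 7.5 and 2.5
  models <- list(
    new_toy_model("I1", "G", "chr1", c(100, 500), c(200, 600)),
    new_toy_model("I2", "G", "chr1", c(100, 900), c(200, 1000))
  )
  shared <- shared_exon_table(models)
  ee <- toy_exon_expression(
    data.frame(chrom = "chr1", start = c(100, 500, 900),
               end = c(200, 600, 1000), strand = "+"),
    rbind(c(10, 10), c(4, 4), c(6, 6))
  )
  iexpr <- rbind(I1 = c(3, 3), I2 = c(1, 1))
  colnames(iexpr) <- ee$samples
  m1 <- build_isoform_matrix(models[[1]], ee, iexpr, shared)
  m2 <- build_isoform_matrix(models[[2]], ee, iexpr, shared)
  expect_equal(unname(m1$values[1, ]), c(7.5, 7.5))
  expect_equal(unname(m2$values[1, ]), c(2.5, 2.5))
  # unshared exons pass through unweighted
  expect_equal(unname(m1$values[2, ]), c(4, 4))
  # corrected instances of the shared exon sum back to the raw value
  expect_equal(unname(m1$values[1, ] + m2$values[1, ]), c(10, 10))
})

test_that("zero total abundance makes a shared exon unexpressed", {
  models <- list(
    new_toy_model("I1", "G", "chr1", c(100, 500), c(200, 600)),
    new_toy_model("I2", "G", "chr1", c(100, 900), c(200, 1000))
  )
  shared <- shared_exon_table(models)
  ee <- toy_exon_expression(
    data.frame(chrom = "chr1", start = c(100, 500, 900),
               end = c(200, 600, 1000), strand = "+"),
    rbind(c(10, 10, 10, 10), c(4, 4, 4, 4), c(6, 6, 6, 6))
  )
  # total abundance zero in 3 of 4 samples: shared exon expressed in only
  # 25% of samples and is filtered out of both isoforms
  iexpr <- rbind(I1 = c(3, 0, 0, 0), I2 = c(1, 0, 0, 0))
  colnames(iexpr) <- ee$samples
  m1 <- build_isoform_matrix(models[[1]], ee, iexpr, shared)
  expect_equal(nrow(m1$values), 1L)
  expect_false(any(grepl("100-200", rownames(m1$values))))
})

test_that("fixture matrices equal corrected values recomputed from ground truth", {
  fx <- fixture_cache()
  models <- read_annotation(fx$files$annotation, genes = fx$genes)
  ee <- read_exon_expression(fx$files$exon_expr_normal)
  ie <- read_isoform_expression(fx$files$isoform_expr_normal)
  mats <- suppressMessages(build_isoform_matrices(models, ee, ie))
  expect_length(mats, length(fx$models))

  raw <- fx$raw_exon$normal
  ab <- fx$abundances$normal
  for (iso in c("GENE1.iso1", "GENE2.iso2", "GENE3.iso1")) {
    m <- mats[[iso]]
    gene <- fx$models[[iso]]$gene
    gene_isoforms <- names(fx$models)[vapply(fx$models, function(x) x$gene,
                                             character(1)) == gene]
    ex <- fx$models[[iso]]$exons
    chrom <- fx$models[[iso]]$chrom
    expected <- matrix(NA_real_, nrow(ex), ncol(ab))
    for (e in seq_len(nrow(ex))) {
      key <- paste0(chrom, ":", ex$start[e], "-", ex$end[e], ":+")
      raw_row <- raw$values[key, ]
      # the generator shares only each gene's first exon
      w <- if (e == 1L) {
        ab[iso, ] / colSums(ab[gene_isoforms, , drop = FALSE])
      } else {
        1
      }
      expected[e, ] <- raw_row * w
    }
    expect_equal(unname(m$values), unname(expected), tolerance = 1e-12)
  }
})
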