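test_that("planted dependence yields an edge; independence does not", {
  set.seed(31)
  dep <- simulate_pair(5, 5, 100, c0 = 0.6)
  ind <- simulate_pair(5, 5, 100, dependent = FALSE)
  mats <- list(
    A.iso1 = structure(list(values = dep$x, isoform_id = "A.iso1",
                            gene = "A"), class = "isoform_matrix"),
    B.iso1 = structure(list(values = dep$y, isoform_id = "B.iso1",
                            gene = "B"), class = "isoform_matrix"),
    C.iso1 = structure(list(values = ind$x, isoform_id = "C.iso1",
                            gene = "C"), class = "isoform_matrix"),
    D.iso1 = structure(list(values = ind$y, isoform_id = "D.iso1",
                            gene = "D"), class = "isoform_matrix")
  )
  for (m in names(mats)) {
    colnames(mats[[m]]$values) <- paste0("S", 1:100)
  }
  net <- ldtnet(mats, alpha = 0.05, condition = "normal")
  e <- edges(net)
  key <- paste(e$isoform_a, e$isoform_b)
  expect_true("A.iso1 B.iso1" %in% key)
  expect_false("C.iso1 D.iso1" %in% key)
  expect_equal(nrow(net$tests), 6L)   # all inter-gene pairs tested
  # edge weights are 1 - p for visualization
  expect_equal(e$weight, 1 - e$p_value)
})

test_that("a single gene's isoforms yield no pairs unless intragene is on", {
  set.seed(8)
  m1 <- simulate_pair(4, 4, 50, dependent = FALSE)
  mats <- list(
    G.iso1 = structure(list(values = m1$x, isoform_id = "G.iso1",
                            gene = "G"), class = "isoform_matrix"),
    G.iso2 = structure(list(values = m1$y, isoform_id = "G.iso2",
                            gene = "G"), class = "isoform_matrix")
  )
  for (m in names(mats)) colnames(mats[[m]]$values) <- paste0("S", 1:50)
  net <- ldtnet(mats)
  expect_equal(nrow(net$tests), 0L)
  expect_equal(nrow(edges(net)), 0L)
  net2 <- ldtnet(mats, include_intragene = TRUE)
  expect_equal(nrow(net2$tests), 1L)
})

test_that("pairs violating the dimensional regime are recorded, not dropped", {
  set.seed(9)
  big <- matrix(rnorm(30 * 20), 30, 20)   # p = 30 > n - 1 = 19
  small <- matrix(rnorm(3 * 20), 3, 20)
  mats <- list(
    A.iso1 = structure(list(values = big, isoform_id = "A.iso1",
                            gene = "A"), class = "isoform_matrix"),
    B.iso1 = structure(list(values = small, isoform_id = "B.iso1",
                            gene = "B"), class = "isoform_matrix"),
    C.iso1 = structure(list(values = small * 2 + rnorm(60),
                            isoform_id = "C.iso1", gene = "C"),
                       class = "isoform_matrix")
  )
  for (m in names(mats)) colnames(mats[[m]]$values) <- paste0("S", 1:20)
  net <- ldtnet(mats)
  expect_equal(nrow(net$skipped), 2L)
  expect_match(net$skipped$reason[1L], "n - 1 > max")
  expect_equal(nrow(net$tests), 1L)       # B-C still tested
})

test_that("the differential network is the annotated symmetric difference", {
  # printed worked example: normal {I11-I21, I11-I23, I12-I23},
  # disease {I11-I21, I11-I22, I12-I23} -> lost {I11-I23}, gained {I11-I22}
  normal <- make_net(data.frame(
    isoform_a = c("G1.I11", "G1.I11", "G1.I12"),
    isoform_b = c("G2.I21", "G2.I23", "G2.I23")
  ), condition = "normal")
  disease <- make_net(data.frame(
    isoform_a = c("G1.I11", "G1.I11", "G1.I12"),
    isoform_b = c("G2.I21", "G2.I22", "G2.I23")
  ), condition = "disease")
  d <- diff_network(normal, disease)
  expect_equal(d$lost$isoform_a, "G1.I11")
  expect_equal(d$lost$isoform_b, "G2.I23")
  expect_equal(d$gained$isoform_a, "G1.I11")
  expect_equal(d$gained$isoform_b, "G2.I22")
  expect_equal(nrow(d$common), 2L)
  # lost/gained partition the symmetric difference
  expect_equal(nrow(d$lost) + nrow(d$gained) + 2L * nrow(d$common), 3L + 3L)

  # self-difference is empty for any network
  self <- diff_network(normal, normal)
  expect_equal(nrow(self$lost), 0L)
  expect_equal(nrow(self$gained), 0L)
  expect_equal(nrow(self$common), 3L)

  # disjoint edge sets: everything is lost or gained
  other <- make_net(data.frame(isoform_a = "G3.I31", isoform_b = "G4.I41"),
                    condition = "disease")
  d2 <- diff_network(normal, other)
  expect_equal(nrow(d2$lost), 3L)
  expect_equal(nrow(d2$gained), 1L)
  # the pair was never tested in the normal network
  expect_equal(d2$gained$note, "untestable-in-normal")

  # mismatched alpha makes networks incomparable
  strict <- make_net(data.frame(isoform_a = "G1.I11", isoform_b = "G2.I21"),
                     alpha = 0.01)
  expect_error(diff_network(normal, strict), "alpha")
})

test_that("edges rank by ascending p-value with canonical tie-breaks", {
  net <- make_net(data.frame(
    isoform_a = c("G1.I1", "G1.I2", "G1.I1", "G1.I3"),
    isoform_b = c("G2.I1", "G2.I9", "G2.I2", "G2.I1"),
    p_value = c(0.04, 0.001, 0.01, 0.001)
  ))
  r <- rank_edges(net)
  expect_equal(r$p_value, c(0.001, 0.001, 0.01, 0.04))
  # tie at 0.001 resolved by canonical node-pair order
  expect_equal(r$isoform_a[1:2], c("G1.I2", "G1.I3"))
  expect_equal(nrow(rank_edges(make_net(data.frame(
    isoform_a = character(0), isoform_b = character(0))[0, ],
    non_edges = data.frame(isoform_a = "G1.I1", isoform_b = "G2.I1")))), 0L)
})

test_that("results are invariant under node order and input order", {
  set.seed(12)
  dep <- simulate_pair(4, 4, 60, c0 = 0.7)
  mk <- function(v, id, g) {
    colnames(v) <- paste0("S", seq_len(ncol(v)))
    structure(list(values = v, isoform_id = id, gene = g),
              class = "isoform_matrix")
  }
  mats <- list(mk(dep$x, "A.iso1", "A"), mk(dep$y, "B.iso1", "B"))
  n1 <- ldtnet(mats)
  n2 <- ldtnet(rev(mats))
  expect_equal(n1$tests, n2$tests)
  expect_equal(n1$tests$gene_a, "A")   # canonical orientation
})

test_that("the edge set shrinks monotonically as alpha decreases", {
  set.seed(19)
  mats <- lapply(1:6, function(i) {
    v <- matrix(rnorm(4 * 40), 4, 40)
    colnames(v) <- paste0("S", 1:40)
    structure(list(values = v, isoform_id = paste0("G", i, ".iso1"),
                   gene = paste0("G", i)), class = "isoform_matrix")
  })
  names(mats) <- vapply(mats, function(m) m$isoform_id, character(1))
  keys <- function(net) {
    e <- edges(net)
    paste(e$isoform_a, e$isoform_b)
  }
  prev <- keys(ldtnet(mats, alpha = 0.25))
  for (a in c(0.1, 0.05, 0.01)) {
    cur <- keys(ldtnet(mats, alpha = a))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("benjamini-hochberg adjustment is available as a labelled extension", {
  set.seed(23)
  mats <- lapply(1:5, function(i) {
    v <- matrix(rnorm(3 * 30), 3, 30)
    colnames(v) <- paste0("S", 1:30)
    structure(list(values = v, isoform_id = paste0("G", i, ".iso1"),
                   gene = paste0("G", i)), class = "isoform_matrix")
  })
  net <- ldtnet(mats, p_adjust_method = "BH")
  expect_true("p_adjusted" %in% colnames(net$tests))
  expect_equal(net$tests$p_adjusted,
               p.adjust(net$tests$p_value, method = "BH"))
  expect_true(all(net$tests$p_adjusted >= net$tests$p_value))
})
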