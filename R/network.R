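#' Infer an isoform co-expression network
#'
#' Applies the large-dimensional trace test to every unordered pair of
#' isoform matrices from distinct genes (and, optionally, to same-gene
#' pairs) and places an undirected edge for each rejected independence null.
#' Pairs violating the test's preconditions (e.g. `n - 1 <= max(p, q)` after
#' zero-variance-exon removal) are skipped and recorded, not silently
#' dropped.
#'
#' @param matrices named list of `isoform_matrix` objects (or plain p x n
#'   matrices, in which case the list names serve as both gene and isoform
#'   labels); all must share the same ordered sample axis.
#' @param alpha per-edge significance level (default 0.05).
#' @param include_intragene also test isoform pairs of the same gene
#'   (auto-regulatory relationships); default `FALSE`.
#' @param condition optional condition label (e.g. `"normal"`, `"tumor"`)
#'   stored with the network.
#' @param p_adjust_method optional multiple-testing correction applied to
#'   the pairwise p-values before the edge decision (`p_adj < alpha`); one
#'   of [stats::p.adjust.methods]. The default `"none"` tests each edge at
#'   level `alpha`, the method's standard behaviour; `"BH"` is a
#'   clearly-labelled extension.
#' @return an object of class `ldtnet` with components `nodes` (data frame
#'   `gene`, `isoform_id`), `tests` (one row per tested pair: dimensions,
#'   `L_n`, `statistic`, `p_value`, `edge`), `skipped` (untestable pairs and
#'   reasons), `alpha`, `condition`.
#' @seealso [edges()], [diff_network()], [rank_edges()], [write_network()]
#' @export
ldtnet <- function(matrices, alpha = 0.05, include_intragene = FALSE,
                   condition = NULL, p_adjust_method = "none") {
  stopifnot_scalar_prob(alpha, "alpha")
  matrices <- normalize_matrix_list(matrices)
  if (length(matrices) < 2L) stop("need at least 2 testable isoforms")
  samp <- lapply(matrices, function(m) colnames(m$values))
  for (i in seq_along(matrices)[-1L]) {
    if (!identical(samp[[i]], samp[[1L]])) {
      stop("isoform matrices do not share the same ordered sample axis (",
           matrices[[i]]$isoform_id, " differs)")
    }
  }
  genes <- vapply(matrices, function(m) m$gene, character(1))
  isos <- vapply(matrices, function(m) m$isoform_id, character(1))
  ord <- order(genes, isos)
  matrices <- matrices[ord]
  genes <- genes[ord]
  isos <- isos[ord]

  tests <- list()
  skipped <- list()
  k <- length(matrices)
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!include_intragene && genes[i] == genes[j]) next
      res <- tryCatch(
        withCallingHandlers(
          ldt_test(matrices[[i]], matrices[[j]], alpha = alpha),
          warning = function(w) invokeRestart("muffleWarning")
        ),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          gene_a = genes[i], isoform_a = isos[i],
          gene_b = genes[j], isoform_b = isos[j],
          reason = conditionMessage(res), stringsAsFactors = FALSE
        )
      } else {
        tests[[length(tests) + 1L]] <- data.frame(
          gene_a = genes[i], isoform_a = isos[i],
          gene_b = genes[j], isoform_b = isos[j],
          p = res$parameter[["p"]], q = res$parameter[["q"]],
          n = res$parameter[["n"]],
          L_n = res$estimate[["L_n"]], statistic = res$statistic[["T"]],
          p_value = res$p.value, edge = res$edge, stringsAsFactors = FALSE
        )
      }
    }
  }
  tests <- if (length(tests) > 0L) do.call(rbind, tests) else empty_tests_df()
  skipped <- if (length(skipped) > 0L) {
    do.call(rbind, skipped)
  } else {
    data.frame(gene_a = character(0), isoform_a = character(0),
               gene_b = character(0), isoform_b = character(0),
               reason = character(0))
  }
  rownames(tests) <- NULL
  rownames(skipped) <- NULL
  if (p_adjust_method != "none" && nrow(tests) > 0L) {
    tests$p_adjusted <- stats::p.adjust(tests$p_value,
                                        method = p_adjust_method)
    tests$edge <- tests$p_adjusted < alpha
  }
  structure(
    list(
      nodes = data.frame(gene = genes, isoform_id = isos,
                         stringsAsFactors = FALSE),
      tests = tests, skipped = skipped,
      alpha = alpha, include_intragene = include_intragene,
      p_adjust_method = p_adjust_method,
      condition = condition %||% NA_character_,
      n_samples = length(samp[[1L]]),
      call = match.call()
    ),
    class = "ldtnet"
  )
}

empty_tests_df <- function() {
  data.frame(gene_a = character(0), isoform_a = character(0),
             gene_b = character(0), isoform_b = character(0),
             p = integer(0), q = integer(0), n = integer(0),
             L_n = numeric(0), statistic = numeric(0),
             p_value = numeric(0), edge = logical(0))
}

normalize_matrix_list <- function(matrices) {
  lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    if (inherits(m, "isoform_matrix")) return(m)
    if (is.matrix(m)) {
      id <- names(matrices)[i] %||% paste0("iso", i)
      if (is.null(colnames(m))) {
        colnames(m) <- paste0("S", seq_len(ncol(m)))
      }
      return(structure(
        list(values = m, isoform_id = id, gene = id,
             exon_keys = rownames(m), sample_ids = colnames(m)),
        class = "isoform_matrix"
      ))
    }
    stop("element ", i, " is neither an isoform_matrix nor a matrix")
  })
}

#' Significant edges of a network
#'
#' @param x an `ldtnet` object.
#' @return data frame of edges (tests with a positive decision), carrying a
#'   `weight` column `1 - p_value` for visualization; ranking should use the
#'   raw p-values (see [rank_edges()]).
#' @export
edges <- function(x) {
  stopifnot(inherits(x, "ldtnet"))
  e <- x$tests[x$tests$edge, , drop = FALSE]
  e$weight <- 1 - e$p_value
  rownames(e) <- NULL
  e
}

#' @export
print.ldtnet <- function(x, ...) {
  cat("Isoform co-expression network",
      if (!is.na(x$condition)) paste0("(", x$condition, ")"), "\n")
  cat("  nodes: ", nrow(x$nodes), " isoform(s), ",
      length(unique(x$nodes$gene)), " gene(s); samples: ", x$n_samples,
      "\n", sep = "")
  cat("  pairs tested: ", nrow(x$tests), "; edges at alpha = ", x$alpha,
      ": ", sum(x$tests$edge), "; skipped: ", nrow(x$skipped), "\n", sep = "")
  if (x$p_adjust_method != "none") {
    cat("  p-value adjustment:", x$p_adjust_method, "\n")
  }
  invisible(x)
}

#' @export
summary.ldtnet <- function(object, max_edges = 10L, ...) {
  print(object)
  e <- rank_edges(object)
  if (nrow(e) > 0L) {
    cat("\nTop edges by p-value:\n")
    print(utils::head(
      e[, c("gene_a", "isoform_a", "gene_b", "isoform_b",
            "statistic", "p_value")],
      max_edges
    ), row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Convert a network to an igraph object
#'
#' @param x an `ldtnet` or `ldtnet_diff` object.
#' @return an undirected [igraph::graph] whose vertices are
#'   `gene:isoform_id` labels; edges carry `statistic`, `p_value`, `weight`
#'   (and `status` for differential networks).
#' @export
as_igraph <- function(x) {
  lab <- function(gene, iso) {
    if (length(gene) == 0L) character(0) else paste0(gene, ":", iso)
  }
  if (inherits(x, "ldtnet")) {
    e <- edges(x)
    verts <- lab(x$nodes$gene, x$nodes$isoform_id)
    ed <- data.frame(from = lab(e$gene_a, e$isoform_a),
                     to = lab(e$gene_b, e$isoform_b),
                     statistic = e$statistic, p_value = e$p_value,
                     weight = e$weight, stringsAsFactors = FALSE)
    return(igraph::graph_from_data_frame(ed, directed = FALSE,
                                         vertices = verts))
  }
  if (inherits(x, "ldtnet_diff")) {
    e <- rbind(
      cbind(x$lost, status = if (nrow(x$lost)) "lost" else character(0)),
      cbind(x$gained, status = if (nrow(x$gained)) "gained" else character(0))
    )
    verts <- unique(c(lab(e$gene_a, e$isoform_a), lab(e$gene_b, e$isoform_b)))
    ed <- data.frame(from = lab(e$gene_a, e$isoform_a),
                     to = lab(e$gene_b, e$isoform_b),
                     p_value = e$p_value,
                     status = if (nrow(e)) e$status else character(0),
                     stringsAsFactors = FALSE)
    return(igraph::graph_from_data_frame(ed, directed = FALSE,
                                         vertices = verts))
  }
  stop("cannot convert object of class ", class(x)[1L], " to igraph")
}

#' @export
plot.ldtnet <- function(x, ...) {
  g <- as_igraph(x)
  igraph::plot.igraph(
    g,
    edge.width = 1 + 3 * igraph::E(g)$weight,
    vertex.label.cex = 0.8, ...
  )
  invisible(x)
}

#' Differential network between two conditions
#'
#' Removes the edges common to two condition-specific networks and returns
#' the remainder partitioned by condition of origin: `lost` edges are
#' present only in the first (reference, e.g. normal) network, `gained`
#' edges only in the second (e.g. disease). Edge identity is the canonical
#' unordered (gene, isoform) node pair. Isoform pairs untestable in the
#' opposite condition are annotated, since their loss/gain cannot be
#' distinguished from missing data.
#'
#' @param net_a reference-condition `ldtnet` (e.g. normal).
#' @param net_b contrast-condition `ldtnet` (e.g. disease); must use the
#'   same `alpha` (networks built at different levels are not comparable).
#' @return an object of class `ldtnet_diff` with data frames `lost`,
#'   `gained` and `common` (each carrying the test results from its network
#'   of origin and a `note` column flagging untestable-in-the-other-condition
#'   edges).
#' @export
diff_network <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "ldtnet"), inherits(net_b, "ldtnet"))
  if (!isTRUE(all.equal(net_a$alpha, net_b$alpha))) {
    stop("networks were built at different alpha levels (", net_a$alpha,
         " vs ", net_b$alpha, ") and are not comparable")
  }
  ea <- edges(net_a)
  eb <- edges(net_b)
  key_a <- pair_key(ea$gene_a, ea$isoform_a, ea$gene_b, ea$isoform_b)
  key_b <- pair_key(eb$gene_a, eb$isoform_a, eb$gene_b, eb$isoform_b)
  tested_a <- pair_key(net_a$tests$gene_a, net_a$tests$isoform_a,
                       net_a$tests$gene_b, net_a$tests$isoform_b)
  tested_b <- pair_key(net_b$tests$gene_a, net_b$tests$isoform_a,
                       net_b$tests$gene_b, net_b$tests$isoform_b)
  lost <- ea[!key_a %in% key_b, , drop = FALSE]
  gained <- eb[!key_b %in% key_a, , drop = FALSE]
  common <- ea[key_a %in% key_b, , drop = FALSE]
  lab_a <- if (is.na(net_a$condition)) "condition-A" else net_a$condition
  lab_b <- if (is.na(net_b$condition)) "condition-B" else net_b$condition
  lost$note <- ifelse(
    pair_key(lost$gene_a, lost$isoform_a, lost$gene_b, lost$isoform_b) %in%
      tested_b, "", paste0("untestable-in-", lab_b))
  gained$note <- ifelse(
    pair_key(gained$gene_a, gained$isoform_a, gained$gene_b,
             gained$isoform_b) %in% tested_a,
    "", paste0("untestable-in-", lab_a))
  common$note <- rep("", nrow(common))
  rownames(lost) <- rownames(gained) <- rownames(common) <- NULL
  structure(
    list(lost = lost, gained = gained, common = common,
         alpha = net_a$alpha, condition_a = lab_a, condition_b = lab_b),
    class = "ldtnet_diff"
  )
}

#' @export
print.ldtnet_diff <- function(x, ...) {
  cat("Differential co-expression network: ", x$condition_a, " vs ",
      x$condition_b, " (alpha = ", x$alpha, ")\n", sep = "")
  cat("  lost in ", x$condition_b, ":   ", nrow(x$lost), " edge(s)\n",
      sep = "")
  cat("  gained in ", x$condition_b, ": ", nrow(x$gained), " edge(s)\n",
      sep = "")
  cat("  common (removed):", nrow(x$common), "edge(s)\n")
  invisible(x)
}

#' @export
summary.ldtnet_diff <- function(object, ...) {
  print(object)
  d <- rank_edges(object)
  if (nrow(d) > 0L) {
    cat("\nDifferential edges by p-value:\n")
    print(d[, c("status", "gene_a", "isoform_a", "gene_b", "isoform_b",
                "p_value")],
          row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
plot.ldtnet_diff <- function(x, ...) {
  g <- as_igraph(x)
  cols <- ifelse(igraph::E(g)$status == "lost", "red", "blue")
  igraph::plot.igraph(g, edge.color = cols, vertex.label.cex = 0.8, ...)
  invisible(x)
}

#' Rank edges by p-value
#'
#' Orders edges by ascending p-value; ties are broken by the canonical
#' (gene, isoform) node-pair order so the result is deterministic.
#'
#' @param x an `ldtnet` (its significant edges are ranked), an `ldtnet_diff`
#'   (lost and gained edges are pooled, with a `status` column), or any data
#'   frame with a `p_value` column.
#' @return the ordered edge data frame.
#' @export
rank_edges <- function(x) {
  UseMethod("rank_edges")
}

#' @export
rank_edges.ldtnet <- function(x) {
  rank_edges(edges(x))
}

#' @export
rank_edges.ldtnet_diff <- function(x) {
  d <- rbind(
    if (nrow(x$lost)) cbind(x$lost, status = "lost"),
    if (nrow(x$gained)) cbind(x$gained, status = "gained")
  )
  if (is.null(d)) {
    d <- cbind(empty_tests_df(), note = character(0), status = character(0))
  }
  rank_edges(d)
}

#' @export
rank_edges.data.frame <- function(x) {
  if (nrow(x) == 0L) return(x)
  if (!"p_value" %in% colnames(x)) stop("edges carry no 'p_value' column")
  key <- if (all(c("gene_a", "isoform_a", "gene_b", "isoform_b") %in%
                 colnames(x))) {
    pair_key(x$gene_a, x$isoform_a, x$gene_b, x$isoform_b)
  } else {
    seq_len(nrow(x))
  }
  out <- x[order(x$p_value, key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
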