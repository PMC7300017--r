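# PCIT co-expression networks: every gene trio's first-order partial
# correlations set a data-driven tolerance; an edge survives only if no
# trio explains it away.  Display edges additionally require
# |r| >= r_min (0.6 by default), with the sign preserved.

#' Pairwise Pearson correlation matrix of an expression matrix
#'
#' Genes with zero variance are dropped with a warning.
#'
#' @param em An [expression_matrix()] or plain matrix (samples x genes),
#'   at least 3 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(em) {
  m <- unclass(em)
  attr(m, "log2") <- NULL
  if (nrow(m) < 3) stop("correlation needs at least 3 samples")
  v <- apply(m, 2, sd, na.rm = TRUE)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    m <- m[, v > 0, drop = FALSE]
  }
  cor(m, use = "pairwise.complete.obs")
}

#' PCIT edge filter
#'
#' For every trio (x, y, z) the three first-order partial correlations
#' are computed; the trio tolerance is the mean of the three
#' partial-to-direct ratios; the x-y association is flagged
#' non-significant for that trio when `|r_xy| < |eps r_xz|` and
#' `|r_xy| < |eps r_yz|`.  An edge is kept iff no trio flags it.
#' Degenerate trios (some |r| = 1, undefined partials) are skipped with
#' a warning.
#'
#' @param R Correlation matrix (symmetric, unit diagonal, >= 3 genes
#'   for the filter to have any effect).
#' @return Logical matrix `kept` (same dimnames, diagonal `FALSE`).
#' @export
pcit_filter <- function(R) {
  g <- ncol(R)
  kept <- matrix(TRUE, g, g, dimnames = dimnames(R))
  diag(kept) <- FALSE
  if (g < 3) return(kept)
  degenerate <- FALSE
  for (x in seq_len(g - 1)) {
    for (y in (x + 1):g) {
      rxy <- R[x, y]
      zs <- setdiff(seq_len(g), c(x, y))
      rxz <- R[x, zs]
      ryz <- R[y, zs]
      bad <- abs(rxy) >= 1 | abs(rxz) >= 1 | abs(ryz) >= 1
      if (any(bad)) degenerate <- TRUE
      rxz <- rxz[!bad]; ryz <- ryz[!bad]
      if (!length(rxz)) next
      rxy_z <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
      rxz_y <- (rxz - rxy * ryz) / sqrt((1 - rxy^2) * (1 - ryz^2))
      ryz_x <- (ryz - rxy * rxz) / sqrt((1 - rxy^2) * (1 - rxz^2))
      eps <- (rxy_z / rxy + rxz_y / rxz + ryz_x / ryz) / 3
      flagged <- abs(rxy) < abs(eps * rxz) & abs(rxy) < abs(eps * ryz)
      if (any(flagged)) {
        kept[x, y] <- kept[y, x] <- FALSE
      }
    }
  }
  if (degenerate) {
    warning("trio(s) with |r| = 1 skipped (partial correlations undefined)")
  }
  kept
}

#' Threshold the PCIT-filtered network and compute degrees
#'
#' Retains kept edges with `|r| >= r_min`, drops isolated nodes and
#' returns the edge list (signed correlations) with node degrees.
#'
#' @param R Correlation matrix.
#' @param kept Logical mask from [pcit_filter()].
#' @param r_min Magnitude threshold on the displayed correlation
#'   (default 0.6).
#' @return List of class `coexpression_network`: `edges` (data frame
#'   `gene_i`, `gene_j`, `r`, `sign`), `degree` (named vector over
#'   retained nodes) and `r_min`.
#' @export
threshold_network <- function(R, kept, r_min = 0.6) {
  idx <- which(kept & upper.tri(R) & abs(R) >= r_min, arr.ind = TRUE)
  edges <- data.frame(
    gene_i = rownames(R)[idx[, 1]],
    gene_j = colnames(R)[idx[, 2]],
    r = R[idx],
    sign = ifelse(R[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
  degree <- vapply(nodes, function(n) {
    sum(edges$gene_i == n | edges$gene_j == n)
  }, numeric(1))
  structure(list(edges = edges, degree = degree, r_min = r_min),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("co-expression network: %d nodes, %d edges (|r| >= %.2f after PCIT)\n",
              length(x$degree), nrow(x$edges), x$r_min))
  invisible(x)
}

#' Export a co-expression network as edge-list TSV and GraphML
#'
#' @param net A [threshold_network()] result.
#' @param edge_path Path for the TSV edge list (`NULL` to skip).
#' @param graphml_path Path for the GraphML file with a `degree` node
#'   attribute (`NULL` to skip).
#' @return Invisibly, the igraph object.
#' @export
export_network <- function(net, edge_path = NULL, graphml_path = NULL) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_i", "gene_j", "r", "sign")], directed = FALSE,
    vertices = data.frame(name = names(net$degree),
                          degree = unname(net$degree)))
  if (!is.null(edge_path)) {
    write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(g)
}

#' Build a PCIT co-expression network from expression data
#'
#' Convenience chain: [correlation_matrix()] then [pcit_filter()] then
#' [threshold_network()].
#'
#' @param em Expression matrix (samples x genes).
#' @param r_min Display threshold on |r| (default 0.6).
#' @return A `coexpression_network` with the correlation matrix and
#'   kept-mask attached as `R` and `kept`.
#' @export
pcit_network <- function(em, r_min = 0.6) {
  R <- correlation_matrix(em)
  kept <- pcit_filter(R)
  net <- threshold_network(R, kept, r_min = r_min)
  net$R <- R
  net$kept <- kept
  net
}
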