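#' Pairwise Pearson correlation matrix of gene expression profiles
#'
#' @param em an [expression_matrix()] (normally the filtered one).
#' @param sample_scope `"all"` correlates across every sample; `"case_only"`
#'   restricts to case samples.
#' @return Symmetric numeric matrix of Pearson correlation coefficients with
#'   unit diagonal.
#' @export
correlation_matrix <- function(em, sample_scope = c("all", "case_only")) {
  sample_scope <- match.arg(sample_scope)
  vals <- em$values
  if (sample_scope == "case_only") {
    vals <- vals[, em$condition == "case", drop = FALSE]
  }
  if (ncol(vals) < 3) stop("need at least 3 samples to correlate")
  sds <- apply(vals, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s) in correlation scope: ",
         paste(rownames(vals)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(vals))
  diag(r) <- 1
  r
}

#' Build the signed co-expression network
#'
#' An edge joins genes i and j when the correlation magnitude reaches
#' `pcc_floor` (closed rule, `>=`) and the BH-adjusted correlation p-value
#' (t-transform with `n_samples - 2` degrees of freedom) is below
#' `alpha_edge`. Edge weights keep the sign of the correlation. Nodes that
#' end up with no edge remain in the node set and are listed in `isolated`.
#'
#' @param corr symmetric correlation matrix (see [correlation_matrix()]).
#' @param pcc_floor minimum `|PCC|` for an edge (default 0.6).
#' @param alpha_edge FDR level for edge significance (default 0.05).
#' @param n_samples number of samples the correlations were computed over.
#' @return A `correlation_network`: list with `nodes`, `edges` (data frame
#'   from/to/weight/p/q), `isolated`, and `params`.
#' @export
build_network <- function(corr, pcc_floor = 0.6, alpha_edge = 0.05,
                          n_samples) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr), n_samples > 3)
  nodes <- rownames(corr)
  if (is.null(nodes)) stop("correlation matrix must carry gene rownames")
  ut <- upper.tri(corr)
  idx <- which(ut, arr.ind = TRUE)
  r <- corr[ut]
  r_clamped <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_clamped * sqrt((n_samples - 2) / (1 - r_clamped^2))
  p <- 2 * stats::pt(-abs(tstat), df = n_samples - 2)
  q <- stats::p.adjust(p, method = "BH")
  keep <- abs(r) >= pcc_floor & q < alpha_edge
  if (!any(keep)) {
    stop("no edge passes |PCC| >= ", pcc_floor, " at alpha_edge = ",
         alpha_edge, "; consider a lower floor")
  }
  edges <- data.frame(from = nodes[idx[keep, 1]],
                      to = nodes[idx[keep, 2]],
                      weight = r[keep],
                      p = p[keep], q = q[keep],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  correlation_network(nodes, edges,
                      params = list(pcc_floor = pcc_floor,
                                    alpha_edge = alpha_edge,
                                    n_samples = n_samples))
}

#' @rdname build_network
#' @param nodes character vector of gene ids.
#' @param edges data frame with columns from, to, weight (and optionally
#'   p, q).
#' @param params list recording the edge criterion actually used.
#' @export
correlation_network <- function(nodes, edges, params = list()) {
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
            all(edges$from != edges$to),
            all(abs(edges$weight) <= 1))
  connected <- unique(c(edges$from, edges$to))
  structure(list(nodes = nodes,
                 edges = edges,
                 isolated = setdiff(nodes, connected),
                 params = params),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "correlation_network: %d nodes, %d edges (%d negative), %d isolated\n",
    length(x$nodes), nrow(x$edges), sum(x$edges$weight < 0),
    length(x$isolated)))
  invisible(x)
}

## igraph view of the network (unweighted topology + signed weight attribute)
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$weight <- net$edges$weight
  g
}

## named adjacency list: for each node, its neighbors and signed weights
adjacency_list <- function(net) {
  adj <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  for (nm in net$nodes) adj[[nm]] <- character(0)
  wts <- stats::setNames(vector("list", length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0) {
    both <- data.frame(
      a = c(net$edges$from, net$edges$to),
      b = c(net$edges$to, net$edges$from),
      w = c(net$edges$weight, net$edges$weight),
      stringsAsFactors = FALSE)
    adj_split <- split(both$b, both$a)
    wts_split <- split(both$w, both$a)
    adj[names(adj_split)] <- adj_split
    wts[names(wts_split)] <- wts_split
  }
  list(neighbors = adj, weights = wts)
}

#' Write / read a network edge list as TSV
#'
#' @param net a `correlation_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
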