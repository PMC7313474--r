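# Small fixtures built in code.

## tiny expression matrix with explicit values
toy_em <- function(values, n_case = NULL) {
  if (is.null(n_case)) n_case <- floor(ncol(values) / 2)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  }
  cond <- stats::setNames(
    c(rep("case", n_case), rep("control", ncol(values) - n_case)),
    colnames(values))
  expression_matrix(values, cond)
}

random_em <- function(n_genes, n_samples, seed = 1, n_case = NULL) {
  set.seed(seed)
  toy_em(matrix(rnorm(n_genes * n_samples), nrow = n_genes),
         n_case = n_case)
}

## random correlation_network with signed weights (Erdos-Renyi topology)
random_network <- function(n, p_edge = 0.2, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample(length(keep), 1)] <- TRUE
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                      weight = stats::runif(sum(keep), -1, 1),
                      stringsAsFactors = FALSE)
  correlation_network(nodes, edges)
}

## random module assignment as used by the cartography statistics
random_partition <- function(nodes, k, seed = 1) {
  set.seed(seed)
  assignment <- stats::setNames(sample(seq_len(k), length(nodes),
                                       replace = TRUE), nodes)
  ## ensure all k labels occur
  assignment[seq_len(min(k, length(nodes)))] <- seq_len(min(k, length(nodes)))
  structure(list(assignment = assignment, k = k, sse = 0,
                 replicate_count = 1),
            class = "community_partition")
}

## explicit small network from an edge string like "A-B,B-C"
edge_network <- function(edge_string, weights = NULL) {
  pairs <- strsplit(strsplit(edge_string, ",", fixed = TRUE)[[1]], "-",
                    fixed = TRUE)
  edges <- data.frame(from = vapply(pairs, `[[`, "", 1),
                      to = vapply(pairs, `[[`, "", 2),
                      stringsAsFactors = FALSE)
  edges$weight <- if (is.null(weights)) rep(0.9, nrow(edges)) else weights
  correlation_network(sort(unique(c(edges$from, edges$to))), edges)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

## small synthetic study used by several robustness / recovery tests
small_spec <- function(seed) {
  synthetic_spec(n_modules = 3, genes_per_module = 60, n_switch = 12,
                 n_background = 5, n_case = 15, n_control = 15, seed = seed)
}
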