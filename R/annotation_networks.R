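#' Minimum connected subnetwork containing seed genes
#'
#' Heuristic Steiner-style construction on a protein-protein interaction
#' graph: the union of pairwise shortest paths among the seeds, followed by
#' iterative pruning of non-seed leaves. Seeds falling outside the
#' seed-richest connected component cannot be joined and are reported in
#' `excluded_seeds`; seeds absent from the graph in `missing_seeds`.
#'
#' @param ppi an `interaction_table` of undirected PPI edges.
#' @param seeds character vector of seed genes (e.g. switch genes).
#' @return List with `graph` (igraph), `nodes`, `edges` (data frame),
#'   `seeds_used`, `excluded_seeds`, `missing_seeds`.
#' @export
minimum_connected_subnetwork <- function(ppi, seeds) {
  g <- igraph::graph_from_data_frame(ppi$edges[, c("source", "target")],
                                     directed = FALSE)
  seeds <- unique(seeds)
  present <- intersect(seeds, igraph::V(g)$name)
  if (length(present) == 0) stop("no seed gene present in the PPI network")
  comp <- igraph::components(g)
  memb <- comp$membership[present]
  best_comp <- as.integer(names(which.max(table(memb))))
  used <- present[memb == best_comp]
  keep_nodes <- used
  if (length(used) > 1) {
    for (i in seq_len(length(used) - 1)) {
      sp <- igraph::shortest_paths(g, from = used[i],
                                   to = used[(i + 1):length(used)],
                                   output = "vpath")
      keep_nodes <- union(keep_nodes,
                          unlist(lapply(sp$vpath, function(v) v$name)))
    }
  }
  sub <- igraph::induced_subgraph(g, keep_nodes)
  ## prune non-seed leaves until none remain
  repeat {
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg <= 1 & !(names(deg) %in% used)]
    if (length(drop) == 0 || igraph::vcount(sub) <= 1) break
    sub <- igraph::delete_vertices(sub, drop)
  }
  ed <- igraph::as_data_frame(sub, what = "edges")
  list(graph = sub,
       nodes = sort(igraph::V(sub)$name),
       edges = ed,
       seeds_used = sort(used),
       excluded_seeds = sort(setdiff(present, used)),
       missing_seeds = sort(setdiff(seeds, present)))
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of each gene set against a query list: p =
#' P(X >= hits) with population `|universe|`, `total` successes (set members
#' present in the universe) and `|query|` draws, BH-adjusted across the
#' tested sets. Rows are reported sorted by p ascending with the familiar
#' Totals (set size in universe) and Hits (overlap with query) columns.
#'
#' @param query character vector of query genes (e.g. a switch-gene set);
#'   genes outside the universe are dropped with a warning.
#' @param gsc a `gene_set_collection` (see [read_gmt()]).
#' @param universe character vector of background genes.
#' @return Data frame with columns `set_name`, `total`, `hits`, `p`, `q`,
#'   `genes` (comma-separated overlap).
#' @export
ora_hypergeometric <- function(query, gsc, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0) stop("empty universe")
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query gene inside the universe")
  }
  sets <- lapply(gsc$sets, intersect, universe)
  totals <- vapply(sets, length, 1L)
  keep <- totals > 0
  sets <- sets[keep]; totals <- totals[keep]
  if (length(sets) == 0) stop("no gene set overlaps the universe")
  overlap <- lapply(sets, intersect, query)
  hits <- vapply(overlap, length, 1L)
  n_u <- length(universe); n_q <- length(query)
  p <- stats::phyper(hits - 1, totals, n_u - totals, n_q, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(set_name = names(sets),
                    total = totals, hits = hits,
                    p = p, q = q,
                    genes = vapply(overlap,
                                   function(g) paste(sort(g), collapse = ","),
                                   character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$set_name), , drop = FALSE]
}

#' Rank regulators of a query gene set
#'
#' Restricts a directed regulator -> target edge table to targets inside the
#' query, then ranks regulators by degree (distinct query targets) and by
#' betweenness centrality on the (undirected view of the) bipartite
#' regulator-gene network. Regulators with no query target are omitted.
#'
#' @param tf_edges a directed `interaction_table` (regulator -> target).
#' @param query character vector of target genes of interest.
#' @param source_label tag naming the regulator database the edges came
#'   from.
#' @return Data frame of class `regulator_ranking` with columns
#'   `regulator`, `degree`, `betweenness`, `source`.
#' @export
rank_regulators <- function(tf_edges, query, source_label = "db") {
  if (!tf_edges$directed) stop("regulator edges must be directed")
  ed <- tf_edges$edges[tf_edges$edges$target %in% query, , drop = FALSE]
  if (nrow(ed) == 0) {
    return(structure(data.frame(regulator = character(0), degree = integer(0),
                                betweenness = numeric(0),
                                source = character(0)),
                     class = c("regulator_ranking", "data.frame")))
  }
  ed <- ed[!duplicated(ed[, c("source", "target")]), , drop = FALSE]
  degree <- vapply(split(ed$target, ed$source),
                   function(t) length(unique(t)), 1L)
  g <- igraph::graph_from_data_frame(ed[, c("source", "target")],
                                     directed = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  regs <- names(degree)
  out <- data.frame(regulator = regs,
                    degree = as.integer(degree),
                    betweenness = unname(btw[regs]),
                    source = source_label,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, -out$betweenness, out$regulator), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("regulator_ranking", "data.frame"))
}

#' Consensus regulators across databases
#'
#' Venn decomposition of the regulator name sets obtained from two or more
#' databases (e.g. three ChIP/motif resources); the full-intersection region
#' holds the consensus regulators.
#'
#' @param rankings named list of `regulator_ranking` data frames (names are
#'   the source tags) or of character vectors of regulator names.
#' @return A `venn_result` over regulator names.
#' @export
consensus_regulators <- function(rankings) {
  if (length(rankings) < 2) stop("need rankings from at least 2 sources")
  sets <- lapply(rankings, function(r) {
    if (is.data.frame(r)) unique(r$regulator) else unique(as.character(r))
  })
  if (is.null(names(sets))) {
    names(sets) <- vapply(rankings, function(r) {
      if (is.data.frame(r) && nrow(r) > 0) r$source[1] else NA_character_
    }, character(1))
  }
  if (anyDuplicated(names(sets))) stop("duplicate source tags")
  venn_regions(sets)
}

#' Rank chemicals interacting with a query gene set
#'
#' Degree of a chemical is its number of distinct query genes in the
#' chemical -> gene interaction table; chemicals reaching `min_degree` are
#' returned sorted by degree descending (ties alphabetical).
#'
#' @param chem_edges an `interaction_table` of chemical -> gene edges
#'   (source = chemical, target = gene).
#' @param query character vector of genes (e.g. shared switch genes).
#' @param min_degree minimum degree to report (default 4).
#' @return Data frame with columns `chemical`, `degree`, `genes`.
#' @export
rank_chemicals <- function(chem_edges, query, min_degree = 4) {
  ed <- chem_edges$edges[chem_edges$edges$target %in% query, , drop = FALSE]
  if (nrow(ed) == 0) {
    return(data.frame(chemical = character(0), degree = integer(0),
                      genes = character(0)))
  }
  by_chem <- split(ed$target, ed$source)
  degree <- vapply(by_chem, function(g) length(unique(g)), 1L)
  keep <- degree >= min_degree
  out <- data.frame(chemical = names(degree)[keep],
                    degree = as.integer(degree[keep]),
                    genes = vapply(by_chem[keep], function(g)
                      paste(sort(unique(g)), collapse = ","), character(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$chemical), , drop = FALSE]
  rownames(out) <- NULL
  out
}
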