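#' Average shortest path length of a network
#'
#' Unweighted breadth-first shortest paths; the mean path length over all
#' ordered reachable pairs within the largest connected component. A network
#' whose largest component is a single node has APL 0 by convention.
#'
#' @param net a `correlation_network` or an igraph graph.
#' @return The average path length (>= 1 for any component with an edge).
#' @export
average_shortest_path <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  if (igraph::vcount(g) == 0) return(0)
  comp <- igraph::components(g)
  if (max(comp$csize) < 2) return(0)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  igraph::mean_distance(sub, directed = FALSE, weights = NA)
}

#' Node-removal robustness curve
#'
#' Removes growing fractions of a hub class (or of all nodes, for
#' `class_label = "random"`) uniformly at random and records the average
#' shortest path of what remains, averaged over `repeats` random removal
#' orderings.
#'
#' @param net a `correlation_network`.
#' @param cart the matching `node_cartography` table.
#' @param class_label one of `"fight_club"`, `"date"`, `"party"`,
#'   `"random"`.
#' @param fraction_grid increasing removed-node fractions starting at 0
#'   (default 0 to 0.5 by 0.05); fractions are of the class size.
#' @param repeats random orderings to average over (default 20).
#' @param seed RNG seed.
#' @return A data frame of class `removal_curve` with columns
#'   `class_label`, `fraction`, `apl` (mean over repeats), `apl_sd`,
#'   `n_removed`.
#' @export
removal_curve <- function(net, cart, class_label,
                          fraction_grid = seq(0, 0.5, by = 0.05),
                          repeats = 20, seed = NULL) {
  stopifnot(class_label %in% c("fight_club", "date", "party", "random"))
  if (any(fraction_grid > 1)) stop("fractions must not exceed 1")
  stopifnot(all(diff(fraction_grid) > 0), fraction_grid[1] == 0)
  members <- if (class_label == "random") net$nodes
             else cart$gene[cart$hub_class == class_label]
  if (length(members) == 0) {
    stop("class '", class_label, "' has no members")
  }
  if (!is.null(seed)) set.seed(seed)
  g0 <- as_igraph(net)
  n_class <- length(members)
  apl_mat <- matrix(NA_real_, nrow = repeats, ncol = length(fraction_grid))
  for (r in seq_len(repeats)) {
    order_r <- sample(members)
    for (j in seq_along(fraction_grid)) {
      n_rm <- floor(fraction_grid[j] * n_class)
      gg <- if (n_rm == 0) g0
            else igraph::delete_vertices(g0, order_r[seq_len(n_rm)])
      apl_mat[r, j] <- average_shortest_path(gg)
    }
  }
  structure(data.frame(class_label = class_label,
                       fraction = fraction_grid,
                       apl = colMeans(apl_mat),
                       apl_sd = apply(apl_mat, 2, stats::sd),
                       n_removed = floor(fraction_grid * n_class),
                       stringsAsFactors = FALSE),
            class = c("removal_curve", "data.frame"))
}

#' Removal curves for every hub class plus random baseline
#'
#' @inheritParams removal_curve
#' @param classes which curves to compute (defaults to all classes present
#'   plus `"random"`).
#' @return A single stacked data frame of curves.
#' @export
removal_curves <- function(net, cart, classes = NULL,
                           fraction_grid = seq(0, 0.5, by = 0.05),
                           repeats = 20, seed = NULL) {
  if (is.null(classes)) {
    classes <- intersect(c("fight_club", "date", "party"),
                         unique(cart$hub_class))
    classes <- c(classes, "random")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(classes, function(cl) {
    removal_curve(net, cart, cl, fraction_grid, repeats, seed = NULL)
  })
  do.call(rbind, out)
}
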