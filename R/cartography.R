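#' Cartography thresholds
#'
#' Boundaries of the heat-cartography plane and of the hub taxonomy. The
#' switch rule is fixed by the method: Zg < `zg_hub` (2.5), Kpi >
#' `kpi_switch` (0.8), APCC < 0. Region breakpoints on the Kpi axis follow
#' the Guimera-Amaral cartography convention. `zg_strong_hub` records the
#' stricter "Zg exceeds 5" hub definition as a separate reporting flag.
#'
#' @param zg_hub boundary between non-hub (R1-R4) and hub (R5-R7) rows of
#'   the plane; also the switch-gene Zg ceiling (default 2.5).
#' @param kpi_switch Kpi floor of region R4 and of switch calling (0.8).
#' @param apcc_party APCC boundary between date and party hubs (0.5).
#' @param zg_strong_hub Zg above which a node is flagged a strong hub (5).
#' @param kpi_nonhub Kpi breakpoints splitting R1/R2/R3/R4 (0.05, 0.62, 0.8).
#' @param kpi_hub Kpi breakpoints splitting R5/R6/R7 (0.30, 0.75).
#' @return List of class `cartography_thresholds`.
#' @export
cartography_thresholds <- function(zg_hub = 2.5, kpi_switch = 0.8,
                                   apcc_party = 0.5, zg_strong_hub = 5,
                                   kpi_nonhub = c(0.05, 0.62, 0.8),
                                   kpi_hub = c(0.30, 0.75)) {
  stopifnot(length(kpi_nonhub) == 3, length(kpi_hub) == 2,
            kpi_nonhub[3] == kpi_switch)
  structure(list(zg_hub = zg_hub, kpi_switch = kpi_switch,
                 apcc_party = apcc_party, zg_strong_hub = zg_strong_hub,
                 kpi_nonhub = kpi_nonhub, kpi_hub = kpi_hub),
            class = "cartography_thresholds")
}

## shared preparation: per-gene z-scored log2 profiles for clustering
zscore_profiles <- function(em) {
  row_zscore(em$values)
}

#' Replicated k-means partition of expression profiles
#'
#' Clusters per-gene z-scored log2 expression profiles with Euclidean
#' k-means, restarting `replicates` times from fresh random centroids and
#' keeping the replicate with the lowest sum of squared errors (SSE).
#' Deterministic for a given `seed`.
#'
#' @param em the filtered [expression_matrix()].
#' @param k number of communities (>= 2).
#' @param replicates number of random restarts (default 100).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return A `community_partition`: list with `assignment` (named integer
#'   vector, module ids 1..k), `k`, `sse`, `replicate_count`, `centers`.
#' @export
kmeans_partition <- function(em, k, replicates = 100, seed = NULL) {
  stopifnot(k >= 2, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- zscore_profiles(em)
  if (k > nrow(x)) stop("k exceeds the number of genes")
  if (k == nrow(x)) {
    ## one gene per cluster: SSE 0 by definition
    return(structure(list(assignment = stats::setNames(seq_len(k),
                                                       rownames(x)),
                          k = k, sse = 0, replicate_count = replicates,
                          centers = x),
                     class = "community_partition"))
  }
  fit <- replicated_kmeans(x, k, replicates)
  structure(list(assignment = stats::setNames(fit$cluster, rownames(x)),
                 k = k, sse = fit$tot.withinss,
                 replicate_count = replicates,
                 centers = fit$centers),
            class = "community_partition")
}

## lowest-SSE k-means over `replicates` fresh random starts; empty-cluster
## failures in a replicate are re-drawn (up to 10 extra attempts)
replicated_kmeans <- function(x, k, replicates) {
  best <- NULL
  for (r in seq_len(replicates)) {
    fit <- NULL
    for (try in 1:10) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = k, iter.max = 100,
                                       nstart = 1)),
        error = function(e) NULL)
      if (!is.null(fit) && length(unique(fit$cluster)) == k) break
      fit <- NULL
    }
    if (is.null(fit)) stop("k-means produced empty clusters repeatedly")
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Choose the community count from an SSE scree curve
#'
#' For each k in `k_range`, runs replicated k-means (keeping the minimum SSE
#' among replicates) and picks the elbow of the min-SSE curve: the k
#' maximizing the second forward difference SSE(k-1) - 2 SSE(k) + SSE(k+1)
#' over interior grid points (ties toward smaller k).
#'
#' @param em the filtered [expression_matrix()].
#' @param k_range integer vector of candidate k (default 2:10; must be
#'   within `[2, n_genes / 10]` to keep communities meaningful).
#' @param replicates random restarts per k (default 20).
#' @param seed RNG seed.
#' @return List with `k` (chosen), `scree` (data frame k vs sse).
#' @export
choose_k_scree <- function(em, k_range = 2:10, replicates = 20, seed = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(em$values)
  k_range <- k_range[k_range >= 2 & k_range <= max(2, floor(n / 10))]
  if (length(k_range) == 0) stop("k_range empty after bounds check")
  if (!is.null(seed)) set.seed(seed)
  x <- zscore_profiles(em)
  sse <- vapply(k_range,
                function(k) replicated_kmeans(x, k, replicates)$tot.withinss,
                numeric(1))
  if (any(diff(sse) > 0)) {
    warning("SSE scree is not monotonically decreasing; ",
            "some k may not have converged")
  }
  if (length(k_range) < 3) {
    k <- k_range[which.min(sse)]
  } else {
    i <- 2:(length(k_range) - 1)
    d2 <- sse[i - 1] - 2 * sse[i] + sse[i + 1]
    k <- k_range[i][which.max(d2)]
  }
  list(k = k, scree = data.frame(k = k_range, sse = sse))
}

## internal degree of every node: number of network neighbors inside the
## node's own module
internal_degrees <- function(net, part) {
  adj <- adjacency_list(net)
  mod <- part$assignment
  vapply(net$nodes, function(v) {
    nb <- adj$neighbors[[v]]
    sum(mod[nb] == mod[[v]])
  }, 1L)
}

#' Within-module degree z-score (Zg)
#'
#' For node i in module m, Zg is the z-score of its internal degree (number
#' of network neighbors inside m) relative to the internal-degree
#' distribution of m (population standard deviation; modules with zero
#' spread give Zg = 0).
#'
#' @param net a `correlation_network`.
#' @param part a `community_partition` covering all network nodes.
#' @return Named numeric vector of Zg.
#' @export
within_module_degree_z <- function(net, part) {
  check_partition(net, part)
  kappa <- internal_degrees(net, part)
  mod <- part$assignment[net$nodes]
  zg <- numeric(length(kappa))
  names(zg) <- net$nodes
  for (m in unique(mod)) {
    idx <- which(mod == m)
    mu <- mean(kappa[idx])
    s <- pop_sd(kappa[idx])
    zg[idx] <- if (s == 0) 0 else (kappa[idx] - mu) / s
  }
  zg
}

#' Clusterphobic coefficient (Kpi)
#'
#' Kpi = 1 - (internal degree / total degree)^2; close to 1 when most of a
#' node's links leave its own module. Isolated nodes (degree 0) get Kpi = 0
#' and are excluded from switch calling.
#'
#' @inheritParams within_module_degree_z
#' @return Named numeric vector of Kpi in `[0, 1]`.
#' @export
clusterphobic_coefficient <- function(net, part) {
  check_partition(net, part)
  adj <- adjacency_list(net)
  kappa <- internal_degrees(net, part)
  ktot <- vapply(net$nodes, function(v) length(adj$neighbors[[v]]), 1L)
  kpi <- ifelse(ktot == 0, 0, 1 - (kappa / pmax(ktot, 1))^2)
  names(kpi) <- net$nodes
  kpi
}

#' Average Pearson correlation with network neighbors (APCC)
#'
#' The arithmetic mean of the signed correlation weights of a node's
#' incident edges. Nodes without neighbors get `NA` (undefined; excluded
#' from hub classification).
#'
#' @param net a `correlation_network`.
#' @return Named numeric vector of APCC in `[-1, 1]` (or `NA`).
#' @export
average_neighbor_correlation <- function(net) {
  adj <- adjacency_list(net)
  apcc <- vapply(net$nodes, function(v) {
    w <- adj$weights[[v]]
    if (length(w) == 0) NA_real_ else mean(w)
  }, numeric(1))
  names(apcc) <- net$nodes
  apcc
}

#' Classify nodes on the heat-cartography plane
#'
#' Assigns each node a hub class from its APCC (fight-club if APCC < 0,
#' party if APCC >= `apcc_party`, date otherwise; `none` when APCC is
#' undefined), a region R1-R7 from its position in the Zg-Kpi plane, and the
#' switch flag: region R4 (Zg below the hub boundary, Kpi > 0.8) with
#' negative APCC.
#'
#' @param zg,kpi,apcc named numeric vectors (same names).
#' @param thresholds a [cartography_thresholds()].
#' @param module optional named module assignment to carry through.
#' @return Data frame of class `node_cartography` with columns `gene`,
#'   `module`, `zg`, `kpi`, `apcc`, `hub_class`, `region`, `is_switch`,
#'   `is_strong_hub`.
#' @export
classify_nodes <- function(zg, kpi, apcc,
                           thresholds = cartography_thresholds(),
                           module = NULL) {
  stopifnot(identical(names(zg), names(kpi)),
            identical(names(zg), names(apcc)))
  th <- thresholds
  hub_class <- rep("none", length(zg))
  hub_class[!is.na(apcc) & apcc < 0] <- "fight_club"
  hub_class[!is.na(apcc) & apcc >= 0 & apcc < th$apcc_party] <- "date"
  hub_class[!is.na(apcc) & apcc >= th$apcc_party] <- "party"

  region <- character(length(zg))
  nonhub <- zg < th$zg_hub
  kn <- th$kpi_nonhub; kh <- th$kpi_hub
  region[nonhub & kpi <= kn[1]] <- "R1"
  region[nonhub & kpi > kn[1] & kpi <= kn[2]] <- "R2"
  region[nonhub & kpi > kn[2] & kpi <= kn[3]] <- "R3"
  region[nonhub & kpi > kn[3]] <- "R4"
  region[!nonhub & kpi <= kh[1]] <- "R5"
  region[!nonhub & kpi > kh[1] & kpi <= kh[2]] <- "R6"
  region[!nonhub & kpi > kh[2]] <- "R7"

  is_switch <- region == "R4" & !is.na(apcc) & apcc < 0
  structure(data.frame(gene = names(zg),
                       module = if (is.null(module)) NA_integer_
                                else as.integer(module[names(zg)]),
                       zg = unname(zg), kpi = unname(kpi),
                       apcc = unname(apcc),
                       hub_class = hub_class, region = region,
                       is_switch = is_switch,
                       is_strong_hub = zg > th$zg_strong_hub,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("node_cartography", "data.frame"))
}

#' Full node cartography of a network under a partition
#'
#' Convenience wrapper computing Zg, Kpi and APCC and classifying every
#' node.
#'
#' @inheritParams within_module_degree_z
#' @param thresholds a [cartography_thresholds()].
#' @return A `node_cartography` data frame (see [classify_nodes()]).
#' @export
node_cartography <- function(net, part,
                             thresholds = cartography_thresholds()) {
  zg <- within_module_degree_z(net, part)
  kpi <- clusterphobic_coefficient(net, part)
  apcc <- average_neighbor_correlation(net)
  classify_nodes(zg, kpi, apcc, thresholds,
                 module = part$assignment)
}

#' Extract the switch-gene set from a cartography table
#'
#' @param cart a `node_cartography` data frame.
#' @param condition_label name of the condition the run describes (e.g.
#'   `"AD"`).
#' @return A `switch_gene_set`: list with `condition`, `genes`
#'   (lexicographically sorted), and `coordinates` (Zg/Kpi/APCC of the
#'   switch genes, for plane plotting).
#' @export
extract_switch_genes <- function(cart, condition_label) {
  genes <- sort(cart$gene[cart$is_switch])
  if (length(genes) == 0) {
    warning("no switch genes called for condition ", condition_label)
  }
  structure(list(condition = condition_label,
                 genes = genes,
                 coordinates = cart[match(genes, cart$gene),
                                    c("gene", "zg", "kpi", "apcc")]),
            class = "switch_gene_set")
}

#' @export
print.switch_gene_set <- function(x, ...) {
  cat(sprintf("switch_gene_set '%s': %d genes\n", x$condition,
              length(x$genes)))
  if (length(x$genes) > 0) {
    cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
        if (length(x$genes) > 10) "..." else "", "\n")
  }
  invisible(x)
}

check_partition <- function(net, part) {
  if (!all(net$nodes %in% names(part$assignment))) {
    stop("partition does not cover all network nodes")
  }
  invisible(TRUE)
}
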