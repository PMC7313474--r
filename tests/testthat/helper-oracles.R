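# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles.

## Benjamini-Hochberg step-up, spelled out: q_(i) = min_{k >= i} m p_(k) / k
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(k) m * p[ord[k]] / k, 1))
  }
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

## Pearson correlation from the raw definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

## all-pairs shortest paths by Floyd-Warshall on an unweighted edge list
floyd_warshall_oracle <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

## APL over ordered reachable pairs of the largest component, from the
## Floyd-Warshall matrix
apl_oracle <- function(nodes, edges) {
  if (length(nodes) == 0) return(0)
  d <- floyd_warshall_oracle(nodes, edges)
  reach <- is.finite(d)
  comp_sizes <- rowSums(reach)
  big <- which.max(comp_sizes)
  members <- which(reach[big, ])
  if (length(members) < 2) return(0)
  dd <- d[members, members]
  mean(dd[row(dd) != col(dd)])
}

## hypergeometric upper tail by direct combinatorial enumeration
hyper_oracle <- function(hits, total, n_universe, n_query) {
  ks <- hits:min(total, n_query)
  sum(vapply(ks, function(k) {
    choose(total, k) * choose(n_universe - total, n_query - k) /
      choose(n_universe, n_query)
  }, 1))
}

## per-node cartography statistics by explicit adjacency walks
cartography_oracle <- function(net, assignment) {
  nodes <- net$nodes
  out <- data.frame(gene = nodes, kappa = 0L, ktot = 0L,
                    apcc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    hit <- net$edges$from == v | net$edges$to == v
    nb <- ifelse(net$edges$from[hit] == v, net$edges$to[hit],
                 net$edges$from[hit])
    out$ktot[i] <- length(nb)
    out$kappa[i] <- sum(assignment[nb] == assignment[[v]])
    if (length(nb) > 0) out$apcc[i] <- mean(net$edges$weight[hit])
  }
  zg <- numeric(length(nodes))
  for (m in unique(assignment[nodes])) {
    idx <- which(assignment[nodes] == m)
    kap <- out$kappa[idx]
    mu <- mean(kap)
    s <- sqrt(mean((kap - mu)^2))
    zg[idx] <- if (s == 0) rep(0, length(idx)) else (kap - mu) / s
  }
  out$zg <- zg
  out$kpi <- ifelse(out$ktot == 0, 0, 1 - (out$kappa / pmax(out$ktot, 1))^2)
  out
}

## naive O(n^3) average-linkage agglomeration returning the cophenetic
## distance matrix
average_linkage_cophenetic_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  dist_cl <- function(a, b) {
    mean(d[clusters[[a]], clusters[[b]]])
  }
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (i in idx) for (j in idx) {
      if (i < j) {
        dij <- dist_cl(i, j)
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    a <- best[1]; b <- best[2]
    for (x in clusters[[a]]) for (y in clusters[[b]]) {
      coph[x, y] <- best_d; coph[y, x] <- best_d
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active[b] <- FALSE
  }
  coph
}

## betweenness by explicit enumeration of all shortest paths (BFS path
## counting on an undirected edge list)
betweenness_oracle <- function(nodes, edges) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$target[edges$source == v], edges$source[edges$target == v])
  })
  btw <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    ## BFS from s with path counts
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    sigma <- stats::setNames(rep(0, length(nodes)), nodes)
    preds <- stats::setNames(vector("list", length(nodes)), nodes)
    dist[s] <- 0; sigma[s] <- 1
    queue <- s; order_visited <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- stats::setNames(numeric(length(nodes)), nodes)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
  }
  btw / 2  # undirected: each pair counted twice
}
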