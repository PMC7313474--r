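ppi_from_string <- function(edge_string) {
  pairs <- strsplit(strsplit(edge_string, ",", fixed = TRUE)[[1]], "-",
                    fixed = TRUE)
  interaction_table(data.frame(source = vapply(pairs, `[[`, "", 1),
                               target = vapply(pairs, `[[`, "", 2)),
                    directed = FALSE)
}

test_that("minimum connected subnetwork joins seeds through connectors", {
  ppi <- ppi_from_string("A-B,B-C,C-D,D-E,X-Y")
  res <- minimum_connected_subnetwork(ppi, c("A", "C"))
  expect_setequal(res$nodes, c("A", "B", "C"))  # forced connector B
  expect_true(igraph::is_connected(res$graph))

  adj <- minimum_connected_subnetwork(ppi, c("A", "B"))
  expect_setequal(adj$nodes, c("A", "B"))       # adjacent seeds, no extras

  split_seeds <- minimum_connected_subnetwork(ppi, c("A", "B", "X"))
  expect_equal(split_seeds$excluded_seeds, "X")
  expect_equal(minimum_connected_subnetwork(ppi, c("A", "ZZ"))$missing_seeds,
               "ZZ")
  expect_error(minimum_connected_subnetwork(ppi, "ZZ"), "no seed")
})

test_that("minimum network is connected, covers seeds, bounded by the
           shortest-path union on random graphs", {
  for (s in 1:15) {
    set.seed(300 + s)
    g <- igraph::sample_gnp(40, 0.08)
    igraph::V(g)$name <- sprintf("P%02d", 1:40)
    ed <- igraph::as_data_frame(g)
    if (nrow(ed) == 0) next
    ppi <- interaction_table(data.frame(source = ed$from, target = ed$to),
                             directed = FALSE)
    seeds <- sample(sprintf("P%02d", 1:40), 5)
    res <- minimum_connected_subnetwork(ppi, seeds)
    expect_true(igraph::is_connected(res$graph))
    expect_true(all(res$seeds_used %in% res$nodes))
    ## oracle bound: the union of ALL shortest paths among the used seeds
    ## contains any one-path-per-pair construction after pruning
    gg <- igraph::graph_from_data_frame(ppi$edges[, c("source", "target")],
                                        directed = FALSE)
    union_nodes <- res$seeds_used
    su <- res$seeds_used
    if (length(su) > 1) {
      for (i in seq_len(length(su) - 1)) for (j in (i + 1):length(su)) {
        sp <- igraph::all_shortest_paths(gg, su[i], su[j])
        union_nodes <- union(union_nodes,
                             unlist(lapply(sp$vpaths, function(v) v$name)))
      }
    }
    expect_lte(igraph::vcount(res$graph), length(union_nodes))
    expect_true(all(res$nodes %in% union_nodes))
  }
})

test_that("hypergeometric ORA matches closed forms and enumeration", {
  universe <- sprintf("U%02d", 1:20)
  gsc <- structure(list(sets = list(S5 = universe[1:5],
                                    OUT = c("Z1", "Z2"),
                                    MISS = universe[6:8]),
                        descriptions = c(S5 = "", OUT = "", MISS = "")),
                   class = "gene_set_collection")
  ## full overlap of a 5-gene set with a 5-gene query: p = 1 / C(20,5)
  res <- ora_hypergeometric(universe[1:5], gsc, universe)
  expect_false("OUT" %in% res$set_name)  # disjoint from universe -> untested
  row5 <- res[res$set_name == "S5", ]
  expect_equal(row5$total, 5)
  expect_equal(row5$hits, 5)
  expect_equal(row5$p, 1 / choose(20, 5), tolerance = 1e-12)
  ## zero overlap keeps the row with p = 1
  rowm <- res[res$set_name == "MISS", ]
  expect_equal(rowm$hits, 0)
  expect_equal(rowm$p, 1)
  expect_true(all(res$q >= res$p - 1e-15))
  expect_equal(res$p, sort(res$p))  # ranked by p ascending

  ## exact enumeration oracle on random small instances
  set.seed(41)
  for (rep in 1:30) {
    n_u <- sample(10:30, 1)
    uni <- sprintf("g%02d", seq_len(n_u))
    set_g <- sample(uni, sample(2:n_u, 1))
    query <- sample(uni, sample(2:n_u, 1))
    gsc1 <- structure(list(sets = list(S = set_g),
                           descriptions = c(S = "")),
                      class = "gene_set_collection")
    r <- ora_hypergeometric(query, gsc1, uni)
    expect_equal(r$p, hyper_oracle(r$hits, r$total, n_u, length(query)),
                 tolerance = 1e-12)
  }
  expect_error(ora_hypergeometric(character(0), gsc, universe), "empty")
})

tf_table <- function(df) interaction_table(df, directed = TRUE)

test_that("regulator ranking counts distinct query targets", {
  edges <- data.frame(source = c("TF1", "TF1", "TF1", "TF2", "TF2", "TF3"),
                      target = c("G1", "G2", "G3", "G1", "G9", "G9"))
  rk <- rank_regulators(tf_table(edges), c("G1", "G2", "G3"))
  expect_equal(rk$degree[rk$regulator == "TF1"], 3L)
  expect_equal(rk$degree[rk$regulator == "TF2"], 1L)
  expect_false("TF3" %in% rk$regulator)  # no query target
  ## duplicate edges do not inflate the degree
  dup <- rank_regulators(tf_table(rbind(edges, edges)), c("G1", "G2", "G3"))
  expect_equal(dup$degree, rk$degree)
})

test_that("betweenness in the bipartite view matches path-counting oracle", {
  ## star: one gene targeted by many TFs -> the gene is the center
  star <- data.frame(source = paste0("TF", 1:4), target = "G1")
  rk <- rank_regulators(tf_table(star), "G1")
  g <- igraph::graph_from_data_frame(star, directed = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE)
  expect_true(all(btw["G1"] > btw[paste0("TF", 1:4)]))
  expect_equal(unname(rk$betweenness), rep(0, 4))

  set.seed(71)
  for (rep in 1:10) {
    edges <- unique(data.frame(
      source = sample(paste0("TF", 1:5), 12, replace = TRUE),
      target = sample(paste0("G", 1:6), 12, replace = TRUE)))
    query <- paste0("G", 1:6)
    rk2 <- rank_regulators(tf_table(edges), query)
    nodes <- unique(c(edges$source, edges$target))
    oracle <- betweenness_oracle(nodes, edges)
    expect_equal(rk2$betweenness,
                 unname(oracle[rk2$regulator]), tolerance = 1e-9)
  }
})

test_that("consensus regulators reduce to the shared-name region", {
  v <- consensus_regulators(list(enc = c("A", "B"), jas = c("B", "C"),
                                 chea = c("B", "D")))
  expect_equal(venn_region(v, c("enc", "jas", "chea")), "B")
  v2 <- consensus_regulators(list(a = c("X", "Y"), b = c("X", "Y"),
                                  c = c("X", "Y")))
  expect_setequal(venn_region(v2, c("a", "b", "c")), c("X", "Y"))
  expect_equal(sum(v$counts), 4)
  expect_error(consensus_regulators(list(a = "X", a = "Y")), "duplicate")
})

test_that("chemical ranking applies the degree floor and tie-breaks", {
  shared <- c("NEAT1", "LPIN3", "ADCYAP1", "CCDC136", "ITPKB", "PDE4DIP",
              "HIGD1B", "SCARNA22")
  edges <- data.frame(
    source = c(rep("valproic acid", 6), rep("aspirin", 3),
               rep("zed", 5), rep("abc", 5)),
    target = c("NEAT1", "LPIN3", "ADCYAP1", "CCDC136", "ITPKB", "PDE4DIP",
               "NEAT1", "LPIN3", "ITPKB",
               shared[1:5], shared[2:6]))
  rk <- rank_chemicals(tf_table(edges), shared, min_degree = 4)
  expect_equal(rk$chemical[1], "valproic acid")
  expect_equal(rk$degree[1], 6L)
  expect_false("aspirin" %in% rk$chemical)      # degree 3 < 4
  ## degree-5 tie broken alphabetically
  expect_equal(rk$chemical[2:3], c("abc", "zed"))
  ## duplicate edges do not change degrees
  rk_dup <- rank_chemicals(tf_table(rbind(edges, edges)), shared, 4)
  expect_equal(rk_dup$degree, rk$degree)
})
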