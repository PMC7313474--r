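test_that("replicated k-means is deterministic and splits duplicates", {
  ## two exact duplicate profile groups -> perfect split with SSE 0
  base1 <- c(1, 5, 2, 8, 3, 9)
  base2 <- c(9, 1, 8, 2, 7, 1)
  vals <- rbind(t(replicate(5, base1)), t(replicate(5, base2)))
  em <- toy_em(vals)
  part <- kmeans_partition(em, k = 2, replicates = 5, seed = 4)
  expect_equal(part$sse, 0, tolerance = 1e-20)
  expect_equal(length(unique(part$assignment[1:5])), 1)
  expect_equal(length(unique(part$assignment[6:10])), 1)
  expect_false(part$assignment[1] == part$assignment[6])

  em_r <- random_em(40, 6, seed = 9)
  p1 <- kmeans_partition(em_r, 4, replicates = 10, seed = 123)
  p2 <- kmeans_partition(em_r, 4, replicates = 10, seed = 123)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$sse, p2$sse)
})

test_that("partition SSE equals recomputation from centers and assignment", {
  em <- random_em(40, 6, seed = 10)
  part <- kmeans_partition(em, 4, replicates = 10, seed = 5)
  x <- t(apply(em$values, 1, function(r) (r - mean(r)) / sd(r)))
  sse <- sum(vapply(seq_len(nrow(x)), function(i) {
    sum((x[i, ] - part$centers[part$assignment[i], ])^2)
  }, 1))
  expect_equal(part$sse, sse, tolerance = 1e-8)
  ## one gene per cluster -> SSE 0
  em_small <- random_em(6, 5, seed = 2)
  p_all <- kmeans_partition(em_small, 6, replicates = 3, seed = 1)
  expect_equal(p_all$sse, 0, tolerance = 1e-12)
})

test_that("scree elbow finds three well-separated profile groups", {
  set.seed(42)
  base <- matrix(rnorm(3 * 6, sd = 3), nrow = 3)  # three distinct profiles
  vals <- do.call(rbind, lapply(1:3, function(i) {
    t(replicate(30, base[i, ] + rnorm(6, sd = 0.15)))
  }))
  rownames(vals) <- sprintf("G%02d", 1:90)
  em <- toy_em(vals)
  res <- choose_k_scree(em, k_range = 2:8, replicates = 10, seed = 6)
  expect_equal(res$k, 3)
  expect_true(all(diff(res$scree$sse) < 0))
  ## independent SSE curve at each k via direct multi-start kmeans on the
  ## same standardized profiles
  x <- switchscan:::zscore_profiles(em)
  set.seed(60)
  sse_direct <- vapply(2:8, function(k)
    stats::kmeans(x, k, nstart = 20, iter.max = 100)$tot.withinss, 1)
  expect_equal(res$scree$sse, sse_direct, tolerance = 0.05)
  d2 <- sse_direct[1:5] - 2 * sse_direct[2:6] + sse_direct[3:7]
  expect_equal((3:7)[which.max(d2)], 3)
  ## the planted groups are recovered exactly at k = 3
  part <- kmeans_partition(em, 3, replicates = 10, seed = 6)
  expect_equal(length(unique(part$assignment[1:30])), 1)
  expect_equal(length(unique(part$assignment[31:60])), 1)
  expect_equal(length(unique(part$assignment[61:90])), 1)
})

test_that("minimum SSE over more replicates never increases", {
  em <- random_em(60, 5, seed = 33)
  set.seed(1)
  x <- switchscan:::zscore_profiles(em)
  for (k in c(3, 5)) {
    set.seed(7)
    s1 <- switchscan:::replicated_kmeans(x, k, 1)$tot.withinss
    set.seed(7)
    s50 <- switchscan:::replicated_kmeans(x, k, 50)$tot.withinss
    expect_lte(s50, s1 + 1e-12)
  }
})

test_that("within-module degree z-score matches the hand-computed example", {
  ## 5-node module, star around A: internal degrees (4,1,1,1,1)
  net <- edge_network("A-B,A-C,A-D,A-E")
  part <- structure(list(assignment = c(A = 1, B = 1, C = 1, D = 1, E = 1),
                         k = 1), class = "community_partition")
  zg <- within_module_degree_z(net, part)
  expect_equal(unname(zg["A"]), (4 - 1.6) / 1.2)  # population sd
  expect_equal(unname(zg["B"]), (1 - 1.6) / 1.2)

  ## all equal internal degrees -> all zero
  ring <- edge_network("A-B,B-C,C-A")
  part3 <- structure(list(assignment = c(A = 1, B = 1, C = 1), k = 1),
                     class = "community_partition")
  expect_equal(unname(within_module_degree_z(ring, part3)), c(0, 0, 0))

  ## node with no in-module neighbor sits below the module mean
  net2 <- edge_network("A-B,A-C,B-C,D-E")
  part2 <- structure(list(assignment = c(A = 1, B = 1, C = 1, D = 1, E = 2),
                          k = 2), class = "community_partition")
  zg2 <- within_module_degree_z(net2, part2)
  expect_lt(zg2[["D"]], 0)
})

test_that("clusterphobic coefficient follows 1 - (kappa/k)^2", {
  ## A has 1 internal (B) and 4 external links
  net <- edge_network("A-B,A-X1,A-X2,A-X3,A-X4,B-A2")
  assign <- c(A = 1, B = 1, A2 = 1, X1 = 2, X2 = 2, X3 = 2, X4 = 2)
  part <- structure(list(assignment = assign, k = 2),
                    class = "community_partition")
  kpi <- clusterphobic_coefficient(net, part)
  expect_equal(unname(kpi["A"]), 1 - (1 / 5)^2)  # 0.96
  ## all links internal -> 0
  expect_equal(unname(kpi["A2"]), 0)             # single internal link to B
  expect_equal(unname(kpi["B"]), 1 - (2 / 2)^2)  # A and A2 both internal
  ## all links external -> 1
  expect_equal(unname(kpi["X1"]), 1)             # only neighbor A is external
  ## isolated nodes get 0
  net_iso <- correlation_network(c("A", "B", "C"),
                                 data.frame(from = "A", to = "B",
                                            weight = 0.9))
  part_iso <- structure(list(assignment = c(A = 1, B = 1, C = 1), k = 1),
                        class = "community_partition")
  expect_equal(clusterphobic_coefficient(net_iso, part_iso)[["C"]], 0)
})

test_that("APCC is the arithmetic mean of signed neighbor weights", {
  net <- correlation_network(
    c("A", "B", "C", "D"),
    data.frame(from = c("A", "A", "A"), to = c("B", "C", "D"),
               weight = c(0.5, -0.9, -0.2)))
  apcc <- average_neighbor_correlation(net)
  expect_equal(unname(apcc["A"]), -0.2)
  expect_equal(unname(apcc["B"]), 0.5)
  net1 <- correlation_network(c("A", "B"),
                              data.frame(from = "A", to = "B", weight = -1))
  expect_equal(average_neighbor_correlation(net1)[["A"]], -1)
})

test_that("zg, kpi, apcc equal the brute-force oracle on random graphs", {
  for (s in 1:100) {
    n <- sample(5:50, 1)
    net <- random_network(n, p_edge = runif(1, 0.05, 0.4), seed = s)
    part <- random_partition(net$nodes, k = sample(2:4, 1), seed = s + 1)
    oracle <- cartography_oracle(net, part$assignment)
    expect_equal(unname(within_module_degree_z(net, part)), oracle$zg,
                 tolerance = 1e-12)
    expect_equal(unname(clusterphobic_coefficient(net, part)), oracle$kpi,
                 tolerance = 1e-12)
    expect_equal(unname(average_neighbor_correlation(net)), oracle$apcc,
                 tolerance = 1e-12)
  }
})

test_that("internal-degree totals conserve intra-module edge counts", {
  for (s in 1:10) {
    net <- random_network(30, 0.2, seed = s)
    part <- random_partition(net$nodes, 3, seed = s)
    kappa <- switchscan:::internal_degrees(net, part)
    intra <- sum(part$assignment[net$edges$from] ==
                   part$assignment[net$edges$to])
    expect_equal(sum(kappa), 2 * intra)
  }
})

test_that("zg is unaffected by adding a disjoint constant module", {
  net <- random_network(20, 0.3, seed = 14)
  part <- random_partition(net$nodes, 2, seed = 14)
  zg_before <- within_module_degree_z(net, part)
  ## append a separate triangle as module 3
  extra <- data.frame(from = c("Z1", "Z2", "Z3"), to = c("Z2", "Z3", "Z1"),
                      weight = 0.9)
  net2 <- correlation_network(c(net$nodes, "Z1", "Z2", "Z3"),
                              rbind(net$edges[, c("from", "to", "weight")],
                                    extra))
  part2 <- structure(list(assignment = c(part$assignment,
                                         Z1 = 3, Z2 = 3, Z3 = 3), k = 3),
                     class = "community_partition")
  zg_after <- within_module_degree_z(net2, part2)
  expect_equal(zg_after[net$nodes], zg_before)
})

test_that("node classification follows the switch rule on the plane", {
  zg <- c(a = 1.0, b = 3.0, c = 1.0)
  kpi <- c(a = 0.9, b = 0.9, c = 0.9)
  apcc <- c(a = -0.2, b = -0.2, c = 0.3)
  cart <- classify_nodes(zg, kpi, apcc)
  expect_equal(cart$region, c("R4", "R7", "R4"))
  expect_equal(cart$hub_class, c("fight_club", "fight_club", "date"))
  expect_equal(cart$is_switch, c(TRUE, FALSE, FALSE))
  sw <- extract_switch_genes(cart, "AD")
  expect_equal(sw$genes, "a")

  ## party boundary and strong-hub flag
  cart2 <- classify_nodes(c(x = 6), c(x = 0.2), c(x = 0.7))
  expect_equal(cart2$hub_class, "party")
  expect_equal(cart2$region, "R5")
  expect_true(cart2$is_strong_hub)
  expect_false(cart2$is_switch)

  ## all non-negative APCC -> empty switch set with warning
  cart3 <- classify_nodes(c(x = 1), c(x = 0.9), c(x = 0.1))
  expect_warning(sw3 <- extract_switch_genes(cart3, "VaD"), "no switch")
  expect_length(sw3$genes, 0)
})

test_that("switch calls are nested inside fight-club hubs on random runs", {
  for (s in 1:10) {
    net <- random_network(40, 0.15, seed = 100 + s)
    part <- random_partition(net$nodes, 3, seed = s)
    cart <- node_cartography(net, part)
    sw <- cart$gene[cart$is_switch]
    fc <- cart$gene[cart$hub_class == "fight_club"]
    neg <- cart$gene[!is.na(cart$apcc) & cart$apcc < 0]
    expect_true(all(sw %in% fc))
    expect_true(all(fc %in% neg))
    expect_true(all(cart$kpi >= 0 & cart$kpi <= 1))
    ok_apcc <- !is.na(cart$apcc)
    expect_true(all(abs(cart$apcc[ok_apcc]) <= 1))
  }
})
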