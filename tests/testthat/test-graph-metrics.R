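make_weighted <- function(edges, weights, directed = FALSE, n = NULL) {
  verts <- unique(as.vector(edges))
  g <- igraph::graph_from_edgelist(edges, directed = directed)
  if (!is.null(weights)) g <- igraph::set_edge_attr(g, "weight",
                                                    value = weights)
  g
}

test_that("eigencentrality is exact on symmetric toys", {
  g <- igraph::make_full_graph(5)
  g <- igraph::set_vertex_attr(g, "name", value = letters[1:5])
  igraph::E(g)$weight <- rep(0.4, igraph::ecount(g))
  expect_equal(unname(eigencentrality(g)), rep(1, 5), tolerance = 1e-9)

  star <- igraph::make_star(6, mode = "undirected")
  star <- igraph::set_vertex_attr(star, "name", value = letters[1:6])
  igraph::E(star)$weight <- runif(5, 0.2, 1)
  ec <- eigencentrality(star)
  expect_equal(unname(which.max(ec)), 1)
  expect_equal(max(ec), 1)
})

test_that("eigencentrality matches dense eigendecomposition on a path", {
  el <- cbind(c("a", "b", "c"), c("b", "c", "d"))
  g <- make_weighted(el, c(0.5, 0.2, 0.9))
  ec <- eigencentrality(g)
  a <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  v <- eigen(a, symmetric = TRUE)$vectors[, 1]
  v <- abs(v) / max(abs(v))
  expect_equal(unname(ec), unname(v), tolerance = 1e-8)
})

test_that("eigencentrality is invariant to relabeling and weight scale", {
  set.seed(31)
  g <- random_weighted_graph(10, 0.4)
  ec <- eigencentrality(g)
  g2 <- igraph::permute(g, sample(10))
  ec2 <- eigencentrality(g2)
  expect_equal(ec2[names(ec)], ec, tolerance = 1e-8)
  g3 <- igraph::set_edge_attr(g, "weight",
                              value = igraph::E(g)$weight * 37)
  expect_equal(eigencentrality(g3), ec, tolerance = 1e-8)
})

test_that("hub and authority scores behave on a single arc", {
  g <- igraph::graph_from_edgelist(cbind("u", "v"), directed = TRUE)
  igraph::E(g)$weight <- 3
  ha <- hub_authority(g)
  expect_equal(unname(ha$hub), c(1, 0))
  expect_equal(unname(ha$authority), c(0, 1))
})

test_that("hub and authority match a converged HITS iteration", {
  set.seed(12)
  for (rep in 1:5) {
    g <- random_weighted_graph(7, 0.4, directed = TRUE)
    if (igraph::ecount(g) < 2) next
    ha <- hub_authority(g)
    a <- capacity_matrix(g)
    ref <- hits_oracle(a)
    expect_equal(unname(ha$hub), ref$hub, tolerance = 1e-8)
    expect_equal(unname(ha$authority), ref$authority, tolerance = 1e-8)
  }
})

test_that("flow betweenness solves the two-hop path by hand", {
  el <- cbind(c("A", "B"), c("B", "C"))
  g <- make_weighted(el, c(0.5, 0.3))
  fb <- flow_betweenness(g)
  expect_equal(unname(fb["B"]), 0.3)
  expect_equal(unname(fb["A"]), 0)
  expect_equal(unname(fb["C"]), 0)
})

test_that("pendant nodes carry no flow", {
  set.seed(4)
  g <- random_weighted_graph(7, 0.5)
  g <- igraph::add_vertices(g, 1, name = "pendant")
  g <- igraph::add_edges(g, c("pendant", "v1"), weight = 0.7)
  fb <- flow_betweenness(g)
  expect_equal(unname(fb["pendant"]), 0)
})

test_that("flow betweenness equals the brute-force max-flow oracle", {
  set.seed(55)
  for (rep in 1:20) {
    directed <- rep %% 2 == 0
    g <- random_weighted_graph(sample(4:7, 1), 0.5, directed = directed)
    if (igraph::ecount(g) == 0) next
    fb <- flow_betweenness(g)
    ref <- brute_flow_betweenness(capacity_matrix(g), directed)
    expect_equal(unname(fb), ref, tolerance = 1e-9)
  }
})

test_that("largest cliques are found with all ties", {
  g <- igraph::make_full_graph(5)
  g <- igraph::set_vertex_attr(g, "name", value = letters[1:5])
  rep <- largest_cliques_report(g)
  expect_equal(rep$size, 5)
  expect_equal(rep$cliques, list(letters[1:5]))

  # two overlapping 4-cliques on 7 nodes
  cl1 <- t(combn(c("a", "b", "c", "d"), 2))
  cl2 <- t(combn(c("d", "e", "f", "g"), 2))
  g2 <- igraph::graph_from_edgelist(rbind(cl1, cl2), directed = FALSE)
  rep2 <- largest_cliques_report(g2)
  expect_equal(rep2$size, 4)
  expect_equal(rep2$cliques,
               list(c("a", "b", "c", "d"), c("d", "e", "f", "g")))
})

test_that("clique membership frequency counts networks, not cliques", {
  r1 <- list(size = 3, cliques = list(c("a", "b", "c"), c("a", "b", "d")))
  r2 <- list(size = 2, cliques = list(c("a", "e")))
  freq <- membership_frequency(list(r1, r2))
  expect_equal(freq[["a"]], 2L)  # present in both networks, counted once each
  expect_equal(freq[["b"]], 1L)
  expect_equal(freq[["e"]], 1L)
})

test_that("Louvain separates two disconnected triangles with Q = 0.5", {
  g <- igraph::graph_from_edgelist(rbind(
    c("a", "b"), c("b", "c"), c("c", "a"),
    c("x", "y"), c("y", "z"), c("z", "x")), directed = FALSE)
  igraph::E(g)$weight <- rep(1, 6)
  lv <- louvain_communities(g, seed = 1)
  expect_equal(length(unique(lv$membership)), 2)
  expect_equal(length(unique(lv$membership[c("a", "b", "c")])), 1)
  expect_equal(lv$modularity, 0.5, tolerance = 1e-12)
})

test_that("a complete graph is a single community with Q = 0", {
  g <- igraph::make_full_graph(6)
  g <- igraph::set_vertex_attr(g, "name", value = letters[1:6])
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  lv <- louvain_communities(g, seed = 2)
  expect_equal(length(unique(lv$membership)), 1)
  expect_equal(lv$modularity, 0, tolerance = 1e-12)
})

test_that("recomputed modularity agrees with igraph's", {
  set.seed(71)
  for (rep in 1:10) {
    g <- random_weighted_graph(12, 0.3)
    if (igraph::ecount(g) == 0) next
    mem <- sample(1:3, 12, replace = TRUE)
    expect_equal(modularity_score(g, mem),
                 igraph::modularity(g, mem, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("spinglass recovers disconnected cliques and reports its Q", {
  g <- igraph::graph_from_edgelist(rbind(
    t(combn(c("a", "b", "c", "d"), 2)),
    t(combn(c("x", "y", "z", "w"), 2))), directed = FALSE)
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  sg <- spinglass_communities(g, seed = 3)
  expect_equal(length(unique(sg$membership)), 2)
  expect_equal(length(unique(sg$membership[c("a", "b", "c", "d")])), 1)
  expect_equal(sg$modularity, 0.5, tolerance = 1e-12)
})

test_that("spinglass quality is competitive with Louvain on planted blocks", {
  dep <- diag(1, 15, 15)
  vars <- catalog_variables()
  dimnames(dep) <- list(vars, vars)
  block <- rep(c(1, 2), c(7, 8))
  for (i in 1:14) for (j in (i + 1):15)
    if (block[i] == block[j]) dep[i, j] <- dep[j, i] <- 0.6
    else dep[i, j] <- dep[j, i] <- 0.05
  wins <- 0L
  for (s in 1:10) {
    co <- generate_cohort(flat_spec(1500, dep), seed = 400 + s)
    g <- build_physio_network(spearman_matrix(co))
    lv <- louvain_communities(g, seed = s)
    sg <- spinglass_communities(g, seed = s)
    if (sg$modularity >= lv$modularity - 0.02) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("Barrat clustering reduces to the binary coefficient at unit weight", {
  set.seed(91)
  for (rep in 1:10) {
    g <- random_weighted_graph(10, 0.4)
    if (igraph::ecount(g) == 0) next
    g <- igraph::set_edge_attr(g, "weight",
                               value = rep(1, igraph::ecount(g)))
    wc <- weighted_clustering(g, "barrat_local")
    ref <- unname(igraph::transitivity(g, type = "local", isolates = "NaN"))
    ref[is.nan(ref)] <- NA
    expect_equal(unname(wc$local), ref, tolerance = 1e-12)
  }
})

test_that("Barrat clustering matches a hand-evaluated weighted toy", {
  # triangle a-b-c with weights 0.2, 0.4, 0.6 plus pendant d on a
  el <- rbind(c("a", "b"), c("b", "c"), c("c", "a"), c("a", "d"))
  g <- make_weighted(el, c(0.2, 0.4, 0.6, 0.9))
  wc <- weighted_clustering(g, "barrat_local")
  # node b: s = 0.6, k = 2, triangle contributes (0.2 + 0.4)/2 * 2 orderings
  expect_equal(unname(wc$local["b"]), (0.2 + 0.4) / (0.6 * (2 - 1)),
               tolerance = 1e-12)
  # node a: s = 1.7, k = 3; only the (b, c) neighbor pair closes
  expect_equal(unname(wc$local["a"]), (0.2 + 0.6) / (1.7 * 2),
               tolerance = 1e-12)
  expect_true(is.na(wc$local["d"]))
  expect_equal(wc$n_excluded, 1L)
})

test_that("complete weighted graphs have unit local clustering", {
  g <- igraph::make_full_graph(6)
  g <- igraph::set_vertex_attr(g, "name", value = letters[1:6])
  set.seed(14)
  igraph::E(g)$weight <- runif(igraph::ecount(g), 0.1, 1)
  wc <- weighted_clustering(g, "barrat_local")
  expect_equal(unname(wc$local), rep(1, 6), tolerance = 1e-12)
})

test_that("directed weighted clustering reduces to Fagiolo at unit weight", {
  set.seed(17)
  for (rep in 1:10) {
    g <- random_weighted_graph(8, 0.35, directed = TRUE)
    if (igraph::ecount(g) < 3) next
    g <- igraph::set_edge_attr(g, "weight",
                               value = rep(1, igraph::ecount(g)))
    wc <- weighted_clustering(g, "directed_weighted")
    a <- (capacity_matrix(g) != 0) * 1
    expect_equal(unname(wc$local), unname(fagiolo_total_clustering(a)),
                 tolerance = 1e-12)
  }
})

test_that("directed weighted clustering agrees with Barrat when symmetric", {
  set.seed(23)
  gu <- random_weighted_graph(9, 0.5)
  w <- capacity_matrix(gu)
  gd <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                            weighted = TRUE)
  cu <- weighted_clustering(gu, "barrat_local")
  cd <- weighted_clustering(gd, "directed_weighted")
  expect_equal(unname(cd$local), unname(cu$local), tolerance = 1e-12)
})

test_that("topology summary is exact on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  tri <- igraph::set_vertex_attr(tri, "name", value = c("a", "b", "c"))
  igraph::E(tri)$weight <- c(1, 1, 1)
  ts <- topology_summary(tri)
  expect_equal(ts$density, 1)
  expect_equal(ts$transitivity_global, 1)
  expect_equal(ts$char_path_length, 1)
  expect_true(is.na(ts$reciprocity))

  # 10 arcs among which exactly one mutual pair
  el <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 4), c(4, 5), c(5, 6),
              c(6, 7), c(7, 8), c(8, 9), c(9, 10))
  gd <- igraph::graph_from_edgelist(el, directed = TRUE)
  igraph::E(gd)$weight <- rep(2, 10)
  tsd <- topology_summary(gd)
  expect_equal(tsd$reciprocity, 0.2)
  expect_equal(tsd$m, 10)
})

test_that("small-world index is near 1 on Erdos-Renyi graphs", {
  set.seed(61)
  vals <- replicate(100, {
    g <- igraph::sample_gnp(15, 0.5)
    g <- igraph::set_vertex_attr(g, "name",
                                 value = paste0("v", 1:15))
    small_world_index(g)
  })
  expect_gt(mean(vals, na.rm = TRUE), 0.8)
  expect_lt(mean(vals, na.rm = TRUE), 1.2)
})

test_that("clustered graphs score higher small-world indices than rings", {
  ring <- igraph::make_ring(15)
  ring <- igraph::set_vertex_attr(ring, "name", value = paste0("v", 1:15))
  sw_ring <- small_world_index(ring)
  lattice <- igraph::sample_smallworld(1, 15, 2, 0.05)
  lattice <- igraph::set_vertex_attr(lattice, "name",
                                     value = paste0("v", 1:15))
  sw_lat <- small_world_index(lattice)
  expect_gt(sw_lat, sw_ring)
  expect_gt(sw_lat, 1)
})

test_that("centralities are invariant under node relabeling", {
  set.seed(41)
  g <- random_weighted_graph(8, 0.5, directed = TRUE)
  perm <- sample(8)
  g2 <- igraph::permute(g, perm)
  fb <- flow_betweenness(g)
  fb2 <- flow_betweenness(g2)
  expect_equal(fb2[names(fb)], fb, tolerance = 1e-10)
  ha <- hub_authority(g)
  ha2 <- hub_authority(g2)
  expect_equal(ha2$hub[names(ha$hub)], ha$hub, tolerance = 1e-8)
})
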