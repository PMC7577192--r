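# weighted adjacency matrix helper (dense; networks here have <= 15 nodes)
.wadj <- function(g) {
  igraph::as_adjacency_matrix(g, attr = if ("weight" %in%
    igraph::edge_attr_names(g)) "weight" else NULL, sparse = FALSE)
}

#' Eigenvector centrality of a weighted undirected network
#'
#' Node influence score: each node's centrality is proportional to the sum
#' of its neighbors' centralities, i.e. the principal eigenvector of the
#' weighted adjacency matrix. Computed by power iteration from the uniform
#' vector (deterministic) to a tolerance of 1e-10 on the max-norm, and
#' rescaled so the maximum score is 1.
#'
#' @param net weighted `igraph` graph.
#' @param tol convergence tolerance, default 1e-10.
#' @return Named nonnegative numeric vector with maximum 1 (all zeros on an
#'   edgeless graph).
#' @export
eigencentrality <- function(net, tol = 1e-10) {
  a <- .wadj(net)
  nm <- igraph::V(net)$name
  if (igraph::ecount(net) == 0)
    return(stats::setNames(numeric(nrow(a)), nm))
  a <- (a + t(a)) / 2  # symmetric view; undirected graphs are unchanged
  # diagonal shift: keeps the Perron vector but makes its eigenvalue
  # strictly dominant in magnitude, so the iteration also converges on
  # bipartite graphs (where lambda_min = -lambda_max)
  shift <- max(rowSums(a))
  a <- a + diag(shift, nrow(a))
  x <- rep(1, nrow(a))
  for (it in seq_len(100000L)) {
    y <- as.vector(a %*% x)
    y <- y / max(abs(y))
    if (max(abs(y - x)) < tol) break
    x <- y
  }
  y <- pmax(y, 0)
  stats::setNames(y / max(y), nm)
}

#' Hub and authority scores of a directed weighted network
#'
#' The directed generalization of eigencentrality: hub scores are the
#' principal eigenvector of `A %*% t(A)` (only outgoing links count) and
#' authority scores that of `t(A) %*% A`, the fixed point of the HITS
#' iteration. Each vector is rescaled to maximum 1; nodes with no outgoing
#' arcs get hub score 0 (the blank rows of the epsilon matrix).
#'
#' @param net directed weighted `igraph` graph.
#' @return List with named numeric vectors `hub` and `authority`.
#' @export
hub_authority <- function(net) {
  stopifnot(igraph::is_directed(net))
  a <- .wadj(net)
  nm <- igraph::V(net)$name
  zero <- stats::setNames(numeric(nrow(a)), nm)
  if (igraph::ecount(net) == 0) return(list(hub = zero, authority = zero))
  principal <- function(s) {
    v <- eigen(s, symmetric = TRUE)$vectors[, 1]
    if (max(v) < -min(v)) v <- -v
    v <- pmax(v, 0)
    if (max(v) > 0) v / max(v) else v
  }
  list(hub = stats::setNames(principal(a %*% t(a)), nm),
       authority = stats::setNames(principal(t(a) %*% a), nm))
}

#' Flow betweenness centrality
#'
#' A gatekeeping measure: edge weights are read as capacities and, for each
#' node v, the score is the total maximum flow between all pairs of other
#' nodes that is lost when v is removed,
#' `sum over (i, j) of maxflow(i, j; G) - maxflow(i, j; G \ v)`.
#' Pairs are unordered for undirected networks and ordered for directed
#' ones (directed capacities are respected).
#'
#' @param net weighted `igraph` graph with positive weights.
#' @return Named nonnegative numeric vector; isolated and pendant nodes
#'   score 0.
#' @export
flow_betweenness <- function(net) {
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  out <- stats::setNames(numeric(n), nm)
  if (n < 3 || igraph::ecount(net) == 0) return(out)
  directed <- igraph::is_directed(net)
  cap <- igraph::E(net)$weight %||% rep(1, igraph::ecount(net))
  pair_flow_sum <- function(g, vids) {
    gcap <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
    tot <- matrix(0, length(vids), length(vids))
    for (i in seq_along(vids)) {
      for (j in seq_along(vids)) {
        if (i == j || (!directed && j < i)) next
        tot[i, j] <- igraph::max_flow(g, vids[i], vids[j],
                                      capacity = gcap)$value
      }
    }
    tot
  }
  base <- pair_flow_sum(net, seq_len(n))
  for (v in seq_len(n)) {
    others <- setdiff(seq_len(n), v)
    gv <- igraph::delete_vertices(net, v)
    fv <- pair_flow_sum(gv, seq_len(n - 1))
    out[v] <- sum(base[others, others]) - sum(fv)
  }
  out
}

#' Largest cliques of a network
#'
#' Enumerates all maximum-size cliques (every pair of members connected).
#' Directed networks are symmetrized first: connectivity, not direction,
#' defines a clique.
#'
#' @param net `igraph` graph.
#' @return List with `size` (clique size) and `cliques`, a list of sorted
#'   character vectors of member names (all ties of maximum size).
#' @export
largest_cliques_report <- function(net) {
  g <- if (igraph::is_directed(net))
    igraph::as_undirected(net, mode = "collapse", edge.attr.comb = "ignore") else net
  if (igraph::ecount(g) == 0)
    return(list(size = if (igraph::vcount(g) > 0) 1L else 0L,
                cliques = as.list(sort(igraph::V(g)$name))))
  cl <- igraph::largest_cliques(g)
  cliques <- lapply(cl, function(v) sort(igraph::V(g)$name[as.integer(v)]))
  list(size = length(cliques[[1]]),
       cliques = cliques[order(vapply(cliques, paste, "", collapse = ","))])
}

#' Largest-clique membership frequency across networks
#'
#' Counts, per node, in how many of the supplied networks the node belongs
#' to at least one largest clique. With the seven networks of the default
#' analysis (pooled sample plus six age strata) the score ranges 0..7.
#'
#' @param reports list of [largest_cliques_report()] results.
#' @return Named integer vector over the union of node names.
#' @export
membership_frequency <- function(reports) {
  all_nodes <- sort(unique(unlist(lapply(reports, function(r)
    unlist(r$cliques)))))
  counts <- stats::setNames(integer(length(all_nodes)), all_nodes)
  for (r in reports) {
    members <- unique(unlist(r$cliques))
    counts[members] <- counts[members] + 1L
  }
  counts
}

#' Weighted modularity of a partition
#'
#' Newman's Q: the fraction of edge weight within communities minus its
#' expectation under the configuration null,
#' `Q = 1/(2m) * sum_ij (w_ij - s_i s_j / (2m)) delta(c_i, c_j)`.
#' Directed networks are symmetrized as `(W + t(W)) / 2` first.
#'
#' @param net weighted `igraph` graph.
#' @param membership community ids, one per vertex (any label type).
#' @return Q in `[-0.5, 1]`.
#' @export
modularity_score <- function(net, membership) {
  w <- .wadj(net)
  if (igraph::is_directed(net)) w <- (w + t(w)) / 2
  m2 <- sum(w)
  if (m2 == 0) return(0)
  s <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(s, s) / m2) * same) / m2
}

#' Louvain community detection
#'
#' Weighted-modularity Louvain (greedy local moves plus aggregation). The
#' reported modularity is recomputed from scratch on the returned
#' assignment via [modularity_score()], not taken from the optimizer.
#'
#' @param net weighted undirected `igraph` graph.
#' @param seed RNG seed (the vertex-visit order is randomized).
#' @return List with `membership` (named integer vector), `modularity` and
#'   `method`.
#' @export
louvain_communities <- function(net, seed = 1L) {
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(net,
    weights = igraph::E(net)$weight %||% NULL)
  mem <- igraph::membership(cl)
  list(membership = stats::setNames(as.integer(mem), igraph::V(net)$name),
       modularity = modularity_score(net, as.integer(mem)),
       method = "louvain")
}

#' Spinglass community detection
#'
#' Reichardt--Bornholdt Potts-model communities found by simulated
#' annealing, run on the symmetrized weighted graph (arc weights averaged
#' with their reverses). Disconnected inputs are handled per connected
#' component; isolated nodes form singleton communities. The reported
#' modularity is recomputed on the symmetrized graph.
#'
#' @param net weighted `igraph` graph (directed or undirected).
#' @param gamma resolution parameter of the Potts Hamiltonian, default 1.
#' @param seed RNG seed (annealing is stochastic).
#' @return List with `membership`, `modularity` and `method`.
#' @export
spinglass_communities <- function(net, gamma = 1, seed = 1L) {
  w <- .wadj(net)
  if (igraph::is_directed(net)) w <- (w + t(w)) / 2
  gu <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE)
  set.seed(as.integer(seed))
  comp <- igraph::components(gu)
  mem <- integer(igraph::vcount(gu))
  next_id <- 0L
  for (cid in seq_len(comp$no)) {
    vids <- which(comp$membership == cid)
    if (length(vids) == 1) {
      mem[vids] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(gu, vids)
    cl <- igraph::cluster_spinglass(sub, weights = igraph::E(sub)$weight,
                                    gamma = gamma, spins = 25L)
    sub_mem <- as.integer(igraph::membership(cl))
    mem[vids] <- next_id + sub_mem
    next_id <- next_id + max(sub_mem)
  }
  list(membership = stats::setNames(mem, igraph::V(gu)$name),
       modularity = modularity_score(gu, mem),
       method = "spinglass")
}

#' Weighted clustering coefficients
#'
#' Local triangle-density measures on weighted graphs:
#' * `barrat_local` (undirected): Barrat's coefficient
#'   `C_i = 1/(s_i (k_i - 1)) * sum_{j,h} (w_ij + w_ih)/2 a_ij a_ih a_jh`,
#'   which reduces to the binary local clustering coefficient at unit
#'   weights.
#' * `directed_weighted`: the Clemente--Grassi total clustering for
#'   directed weighted graphs, built on the symmetrized weight matrix
#'   `W~ = (W + t(W))/2` and total degrees:
#'   `C_i = [W~ (A + t(A))^2]_ii / (s_i^tot (d_i^tot - 1) - 2 s_i^bil)`,
#'   where `s_i^tot` is total (in+out) strength and `s_i^bil` the strength
#'   carried by bilateral dyads. At unit weights this reduces to Fagiolo's
#'   binary total clustering, and on undirected graphs to Barrat's form.
#'
#' Nodes with fewer than two (total-degree) neighbors have no defined local
#' value; they are excluded from the global mean and counted.
#'
#' @param net weighted `igraph` graph with positive weights.
#' @param mode `"barrat_local"` (undirected input) or `"directed_weighted"`.
#' @return List with `local` (named vector, `NA` where undefined), `global`
#'   (mean over defined nodes), `sem` (standard error of that mean) and
#'   `n_excluded`.
#' @export
weighted_clustering <- function(net,
                                mode = c("barrat_local",
                                         "directed_weighted")) {
  mode <- match.arg(mode)
  w <- .wadj(net)
  a <- (w != 0) * 1
  nm <- igraph::V(net)$name
  if (mode == "barrat_local") {
    if (igraph::is_directed(net))
      stop("barrat_local requires an undirected network")
    s <- rowSums(w)
    k <- rowSums(a)
    num <- diag(w %*% a %*% a)
    denom <- s * (k - 1)
    local <- ifelse(k >= 2, num / denom, NA_real_)
  } else {
    wt <- (w + t(w)) / 2
    aa <- a + t(a)
    num <- diag(wt %*% aa %*% aa)
    s_tot <- rowSums(w) + colSums(w)
    d_tot <- rowSums(a) + colSums(a)
    s_bil <- rowSums(wt * (a * t(a)))
    denom <- s_tot * (d_tot - 1) - 2 * s_bil
    local <- ifelse(denom > 0, num / denom, NA_real_)
  }
  local <- stats::setNames(local, nm)
  ok <- !is.na(local)
  g <- if (any(ok)) mean(local[ok]) else NA_real_
  sem <- if (sum(ok) > 1) stats::sd(local[ok]) / sqrt(sum(ok)) else NA_real_
  list(local = local, global = g, sem = sem, n_excluded = sum(!ok))
}

#' Small-world index
#'
#' `SWI = (CC / CC_rand) / (L / L_rand)` on the binarized (and, for
#' directed inputs, symmetrized) graph, with the closed-form random-graph
#' baselines `CC_rand = p = 2m / (n (n - 1))` and
#' `L_rand = ln(n) / ln(mean degree)`. CC is the mean binary local
#' clustering coefficient over nodes of degree >= 2 and L the mean
#' unweighted shortest-path length over connected pairs. Values well above
#' 1 indicate small-world structure: high clustering with short paths.
#'
#' @param net `igraph` graph.
#' @return The index, or `NA` when the mean degree is 1 or less (the
#'   logarithmic baseline degenerates).
#' @export
small_world_index <- function(net) {
  g <- if (igraph::is_directed(net))
    igraph::as_undirected(net, mode = "collapse", edge.attr.comb = "ignore") else net
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 4 || m == 0) return(NA_real_)
  kbar <- 2 * m / n
  if (kbar <= 1) return(NA_real_)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "NaN")
  cc <- mean(cc_local[!is.nan(cc_local)])
  l <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE,
                             weights = NA)
  cc_rand <- 2 * m / (n * (n - 1))
  l_rand <- log(n) / log(kbar)
  (cc / cc_rand) / (l / l_rand)
}

#' Network-level topology summary
#'
#' One row of global descriptors, unweighted except where stated:
#' * `density`: edges present over edges possible (ordered pairs for
#'   directed graphs).
#' * `reciprocity`: fraction of arcs whose reverse is also present
#'   (directed only, `NA` otherwise).
#' * `char_path_length`: mean hop-count shortest path over connected pairs
#'   (respecting direction in directed graphs); disconnected pairs are
#'   excluded.
#' * `transitivity_global`: 3 x triangles / connected triples on the
#'   binarized, symmetrized graph.
#' * `clustering_binary`: mean binary local clustering coefficient.
#' * `clustering_weighted`: global mean of [weighted_clustering()]
#'   (Barrat for undirected, Clemente--Grassi for directed input).
#' * `small_world`: [small_world_index()].
#'
#' @param net `igraph` graph.
#' @return One-row data frame.
#' @export
topology_summary <- function(net) {
  directed <- igraph::is_directed(net)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  gu <- if (directed) igraph::as_undirected(net, mode = "collapse", edge.attr.comb = "ignore") else net
  cc_local <- if (igraph::ecount(gu) > 0)
    igraph::transitivity(gu, type = "local", isolates = "NaN") else NaN
  cc_bin <- if (all(is.nan(cc_local))) NA_real_
            else mean(cc_local[!is.nan(cc_local)])
  wc <- if (m > 0)
    weighted_clustering(net, if (directed) "directed_weighted"
                             else "barrat_local")$global
  else NA_real_
  data.frame(
    n = n, m = m,
    density = igraph::edge_density(net),
    reciprocity = if (directed) igraph::reciprocity(net) else NA_real_,
    char_path_length = if (m > 0)
      igraph::mean_distance(net, directed = directed, unconnected = TRUE,
                            weights = NA) else NA_real_,
    transitivity_global = if (igraph::ecount(gu) > 0)
      igraph::transitivity(gu, type = "global") else NA_real_,
    clustering_binary = cc_bin,
    clustering_weighted = wc,
    small_world = small_world_index(net)
  )
}
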