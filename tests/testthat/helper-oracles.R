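# Independent reference implementations used to check the package's
# computations. These are deliberately naive (brute force, explicit
# iteration) and share no code with the implementation under test.

# Edmonds-Karp max flow on a dense capacity matrix. Undirected graphs are
# encoded by a symmetric capacity matrix (an edge usable in both
# directions).
ek_max_flow <- function(cap, s, t) {
  n <- nrow(cap)
  flow <- 0
  repeat {
    # BFS for an augmenting path in the residual network
    parent <- rep(NA_integer_, n)
    parent[s] <- s
    queue <- s
    while (length(queue) > 0 && is.na(parent[t])) {
      u <- queue[1]
      queue <- queue[-1]
      for (v in which(cap[u, ] > 1e-12 & is.na(parent))) {
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
    if (is.na(parent[t])) break
    # bottleneck along the path
    aug <- Inf
    v <- t
    while (v != s) {
      u <- parent[v]
      aug <- min(aug, cap[u, v])
      v <- u
    }
    v <- t
    while (v != s) {
      u <- parent[v]
      cap[u, v] <- cap[u, v] - aug
      cap[v, u] <- cap[v, u] + aug
      v <- u
    }
    flow <- flow + aug
  }
  flow
}

# brute-force flow betweenness: all-pairs max flow with and without each
# node, from the capacity matrix
brute_flow_betweenness <- function(cap, directed) {
  n <- nrow(cap)
  pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
  pairs <- pairs[pairs$i != pairs$j, ]
  if (!directed) pairs <- pairs[pairs$i < pairs$j, ]
  base <- apply(pairs, 1, function(p) ek_max_flow(cap, p[1], p[2]))
  out <- numeric(n)
  for (v in seq_len(n)) {
    capv <- cap
    capv[v, ] <- 0
    capv[, v] <- 0
    keep <- pairs$i != v & pairs$j != v
    fv <- apply(pairs[keep, ], 1, function(p) ek_max_flow(capv, p[1], p[2]))
    out[v] <- sum(base[keep]) - sum(fv)
  }
  out
}

# average ranks without rank(): competition ranks averaged over ties
average_ranks <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

# explicit Pearson correlation of the average ranks
spearman_oracle <- function(x, y) {
  rx <- average_ranks(x)
  ry <- average_ranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# normalized HITS iteration on a weighted adjacency matrix
hits_oracle <- function(a, iters = 1000) {
  n <- nrow(a)
  h <- rep(1, n)
  au <- rep(1, n)
  for (k in seq_len(iters)) {
    au <- as.vector(t(a) %*% h)
    if (max(au) > 0) au <- au / max(au)
    h <- as.vector(a %*% au)
    if (max(h) > 0) h <- h / max(h)
  }
  list(hub = h, authority = au)
}

# exhaustive maximum-clique search on a symmetric binary adjacency matrix
exhaustive_largest_cliques <- function(adj) {
  n <- nrow(adj)
  best <- list()
  best_size <- 0
  for (code in 0:(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    k <- length(members)
    if (k < best_size || k == 0) next
    sub <- adj[members, members, drop = FALSE]
    if (all(sub[upper.tri(sub)] == 1)) {
      if (k > best_size) {
        best <- list(members)
        best_size <- k
      } else {
        best <- c(best, list(members))
      }
    }
  }
  best
}

# Fagiolo's binary total clustering for directed graphs
fagiolo_total_clustering <- function(a) {
  aa <- a + t(a)
  t3 <- diag(aa %*% aa %*% aa) / 2
  d_tot <- rowSums(a) + colSums(a)
  d_bi <- diag(a %*% a)
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  ifelse(denom > 0, t3 / denom, NA_real_)
}

# random weighted igraph, uniformly weighted edges
random_weighted_graph <- function(n, p, directed = FALSE) {
  g <- igraph::sample_gnp(n, p, directed = directed)
  if (igraph::ecount(g) > 0)
    g <- igraph::set_edge_attr(g, "weight",
                               value = stats::runif(igraph::ecount(g),
                                                    0.1, 1))
  igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
}

# capacity matrix of a weighted igraph
capacity_matrix <- function(g) {
  igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
}

# small in-memory cohort with explicit values for the 15 variables
toy_cohort <- function(n = 4, age = 40, sex = "M") {
  vars <- catalog_variables()
  base <- c(glucose = 5, hba1c = 5.3, insulin = 55, hdl = 1.4, ldl = 2.5,
            triglycerides = 1.2, uric_acid = 300, urea = 5,
            creatinine = 70, waist = 85, weight = 70, height = 170,
            temperature = 36.6, systolic = 115, diastolic = 75)
  out <- data.frame(participant_id = sprintf("T%03d", seq_len(n)),
                    age = rep_len(age, n),
                    sex = factor(rep_len(sex, n), levels = c("M", "F")),
                    stringsAsFactors = FALSE)
  for (v in vars) out[[v]] <- rep(base[[v]], n)
  out
}

# cohort spec with a single stratum and simple normal marginals
flat_spec <- function(n, dependence, label = "<25",
                      age_min = 18, age_max = 24) {
  vars <- catalog_variables()
  marginals <- data.frame(variable = rep(vars, each = 1), stratum = label,
                          mean = 100, sd = 10, family = "normal",
                          stringsAsFactors = FALSE)
  cohort_spec(
    data.frame(label = label, n = n, age_min = age_min, age_max = age_max,
               stringsAsFactors = FALSE),
    marginals, dependence)
}
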