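#' Pairwise Spearman association matrix
#'
#' Spearman rank correlations between all pairs of physiological variables,
#' computed on pairwise-complete observations with average ranks (so ties
#' are handled exactly), together with two-sided p-values from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` and the
#' per-pair complete-observation counts.
#'
#' Rank correlation is used because biomarker distributions are typically
#' non-normal and monotone association is the quantity of interest; the
#' resulting matrix is invariant under strictly increasing transformations
#' of any variable.
#'
#' @param cohort cohort data frame.
#' @param variables variables to correlate, default the full catalog.
#' @return A list of class `assoc_matrix` with symmetric matrices `rho`
#'   (unit diagonal), `p` and `n_pairs`. Pairs involving a constant variable
#'   get `NA` rho.
#' @export
spearman_matrix <- function(cohort, variables = catalog_variables()) {
  x <- as.matrix(cohort[, variables, drop = FALSE])
  k <- ncol(x)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n_pairs <- matrix(0L, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1
  diag(p) <- 0
  for (i in seq_len(k)) n_pairs[i, i] <- sum(!is.na(x[, i]))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(x[, c(i, j)])
      n <- sum(ok)
      n_pairs[i, j] <- n_pairs[j, i] <- n
      if (n < 3) next
      xi <- rank(x[ok, i])
      xj <- rank(x[ok, j])
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      r <- stats::cor(xi, xj)
      rho[i, j] <- rho[j, i] <- r
      if (abs(r) >= 1) {
        p[i, j] <- p[j, i] <- 0
      } else {
        tstat <- r * sqrt((n - 2) / (1 - r^2))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tstat), n - 2)
      }
    }
  }
  structure(list(rho = rho, p = p, n_pairs = n_pairs),
            class = "assoc_matrix")
}

#' Build the undirected physiological-variables network
#'
#' Nodes are the physiological variables; an edge joins two variables when
#' their Spearman correlation is significant at `alpha` (default 0.001).
#' Edge weights are the squared correlations (rho^2), so that weights are
#' positive; the signed rho is kept as an edge attribute for reporting.
#'
#' @param assoc `assoc_matrix` from [spearman_matrix()].
#' @param alpha significance gate for edge inclusion, default 0.001.
#' @return An undirected weighted `igraph` graph on all variables (isolated
#'   nodes retained) with edge attributes `weight` (rho^2), `rho` and `p`,
#'   and graph attributes `kind = "physio"` and `alpha`.
#' @export
build_physio_network <- function(assoc, alpha = 0.001) {
  stopifnot(inherits(assoc, "assoc_matrix"))
  vars <- rownames(assoc$rho)
  k <- length(vars)
  keep <- !is.na(assoc$p) & assoc$p < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vars)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "rho", value = assoc$rho[idx])
    g <- igraph::set_edge_attr(g, "weight", value = assoc$rho[idx]^2)
    g <- igraph::set_edge_attr(g, "p", value = assoc$p[idx])
  }
  g <- igraph::set_graph_attr(g, "kind", "physio")
  igraph::set_graph_attr(g, "alpha", alpha)
}

#' Binomial co-occurrence z-statistic (epsilon)
#'
#' Tests whether participants in state X are in state C more often than the
#' marginal prevalence of C predicts. With `P(c) = c_count / N` and
#' `P(c|x) = co_count / n_x`, the statistic is the z-score of the observed
#' co-occurrence count against its binomial null:
#' `epsilon = n_x (P(c|x) - P(c)) / sqrt(n_x P(c) (1 - P(c)))`.
#' It is directional: `epsilon(C|X)` and `epsilon(X|C)` share a sign but
#' generally differ in magnitude. Under the normal approximation,
#' `epsilon > 1.96` corresponds to the usual 95% confidence level.
#'
#' @param co_count participants in both X and C.
#' @param n_x participants in X.
#' @param c_count participants in C.
#' @param N participants assessed for both states.
#' @return The z-statistic (vectorized); `NA` when `n_x = 0` or the
#'   prevalence of C is 0 or 1.
#' @examples
#' epsilon_statistic(30, 100, 0.2 * 500, 500) # 2.5
#' @export
epsilon_statistic <- function(co_count, n_x, c_count, N) {
  pc <- c_count / N
  out <- n_x * (co_count / n_x - pc) / sqrt(n_x * pc * (1 - pc))
  out[n_x <= 0 | pc <= 0 | pc >= 1] <- NA_real_
  out
}

#' Epsilon matrix over all ordered state pairs
#'
#' For every ordered pair (X, C) of distinct pathological states,
#' [epsilon_statistic()] computed on the participants with non-missing
#' values for both states (complete-pair basis, so each entry uses its own
#' N).
#'
#' @param states state matrix from [assess_states()].
#' @return A list with `epsilon` (k x k matrix, rows = conditioning state X,
#'   `NA` diagonal), `n_x` (state counts on the full matrix) and
#'   `prevalence` (full-matrix prevalences).
#' @export
epsilon_matrix <- function(states) {
  s <- as.matrix(states)
  k <- ncol(s)
  nm <- colnames(s)
  eps <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      ok <- !is.na(s[, i]) & !is.na(s[, j])
      N <- sum(ok)
      if (N == 0) next
      eps[i, j] <- epsilon_statistic(sum(s[ok, i] & s[ok, j]),
                                     sum(s[ok, i]), sum(s[ok, j]), N)
    }
  }
  n_x <- colSums(s == TRUE, na.rm = TRUE)
  assessed <- colSums(!is.na(s))
  list(epsilon = eps, n_x = n_x,
       prevalence = ifelse(assessed > 0, n_x / assessed, NA_real_))
}

#' Build the directed pathological-states network
#'
#' Nodes are the 12 pathological states; an arc X -> C is present when
#' `epsilon(C|X)` exceeds the threshold (default 1.96, the two-sided 95%
#' normal quantile), weighted by epsilon. Reciprocal arcs may coexist with
#' different weights; states with degenerate prevalence (0 or 1) contribute
#' no arcs.
#'
#' @param states state matrix from [assess_states()].
#' @param threshold arc-inclusion gate on epsilon, default 1.96.
#' @return A directed weighted `igraph` graph on all states with edge
#'   attribute `weight` (epsilon) and graph attributes `kind = "patho"` and
#'   `threshold`.
#' @export
build_patho_network <- function(states, threshold = 1.96) {
  em <- epsilon_matrix(states)
  eps <- em$epsilon
  nm <- rownames(eps)
  keep <- !is.na(eps) & eps > threshold
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(nm), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = nm)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "weight", value = eps[idx])
  }
  g <- igraph::set_graph_attr(g, "kind", "patho")
  igraph::set_graph_attr(g, "threshold", threshold)
}

#' Export a network as an edge-list CSV
#'
#' Columns: source, target, weight, and the signed rho (physiological
#' networks) or epsilon (pathological networks).
#'
#' @param net `igraph` graph from [build_physio_network()] or
#'   [build_patho_network()].
#' @param path output CSV path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   weight = igraph::E(net)$weight %||% rep(1, nrow(el)),
                   stringsAsFactors = FALSE)
  if (!is.null(igraph::E(net)$rho)) df$rho <- igraph::E(net)$rho
  else if (identical(igraph::graph_attr(net, "kind"), "patho"))
    df$epsilon <- df$weight
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
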