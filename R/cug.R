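# built-in graph-level statistics usable by name in cug_test()
.cug_builtins <- function() {
  list(
    density = function(g) igraph::edge_density(g),
    edges = function(g) igraph::ecount(g),
    transitivity = function(g) {
      gu <- if (igraph::is_directed(g))
        igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = "ignore") else g
      t <- igraph::transitivity(gu, type = "global")
      if (is.nan(t)) 0 else t
    },
    reciprocity = function(g) igraph::reciprocity(g),
    char_path_length = function(g)
      igraph::mean_distance(g, directed = igraph::is_directed(g),
                            unconnected = TRUE, weights = NA),
    max_eigencentrality = function(g) max(eigencentrality(g)),
    max_flow_betweenness = function(g) max(flow_betweenness(g)),
    mean_flow_betweenness = function(g) mean(flow_betweenness(g))
  )
}

# draw one random graph under the requested conditioning; returns an
# igraph with the observed weights reassigned at random to the drawn ties
.cug_draw <- function(n, directed, m, conditioning, weights, dyads = NULL) {
  if (directed) {
    pairs <- which(diag(n) == 0, arr.ind = TRUE)  # ordered pairs
  } else {
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  }
  np <- nrow(pairs)
  if (conditioning == "size") {
    sel <- which(stats::runif(np) < 0.5)
  } else if (conditioning == "edges") {
    sel <- if (m > 0) sample.int(np, m) else integer(0)
  } else { # dyad_census, directed only; pairs are unordered here
    ud <- which(upper.tri(diag(n)), arr.ind = TRUE)
    nd <- nrow(ud)
    type <- sample(rep(c("m", "a", "n"),
                       c(dyads$mut, dyads$asym, dyads$null)))
    el <- NULL
    mut_rows <- ud[type == "m", , drop = FALSE]
    if (nrow(mut_rows) > 0)
      el <- rbind(mut_rows, mut_rows[, 2:1, drop = FALSE])
    asym_rows <- ud[type == "a", , drop = FALSE]
    if (nrow(asym_rows) > 0) {
      flip <- stats::runif(nrow(asym_rows)) < 0.5
      asym_rows[flip, ] <- asym_rows[flip, 2:1, drop = FALSE]
      el <- rbind(el, asym_rows)
    }
    g <- igraph::make_empty_graph(n = n, directed = TRUE)
    if (!is.null(el) && nrow(el) > 0) g <- igraph::add_edges(g, t(el))
    if (igraph::ecount(g) > 0 && length(weights) > 0) {
      w <- if (igraph::ecount(g) == length(weights)) sample(weights)
           else sample(weights, igraph::ecount(g), replace = TRUE)
      g <- igraph::set_edge_attr(g, "weight", value = w)
    }
    return(g)
  }
  g <- igraph::make_empty_graph(n = n, directed = directed)
  if (length(sel) > 0) g <- igraph::add_edges(g, t(pairs[sel, , drop = FALSE]))
  if (igraph::ecount(g) > 0 && length(weights) > 0) {
    w <- if (igraph::ecount(g) == length(weights)) sample(weights)
         else sample(weights, igraph::ecount(g), replace = TRUE)
    g <- igraph::set_edge_attr(g, "weight", value = w)
  }
  g
}

#' Conditional uniform graph (CUG) test
#'
#' Monte-Carlo test of whether a graph statistic is larger or smaller than
#' expected in random graphs sharing coarse features of the observed one.
#' Three conditionings are available:
#' * `"size"`: same number of nodes, each possible tie present
#'   independently with probability 1/2;
#' * `"edges"`: same number of nodes and exactly the same number of
#'   ties, drawn uniformly;
#' * `"dyad_census"`: directed only; same counts of mutual, asymmetric and
#'   null dyads, uniform over such digraphs.
#'
#' The binarized structure is randomized; the observed edge weights are
#' reassigned uniformly at random to the drawn ties, so weighted statistics
#' are tested against the structure, holding the weight distribution fixed.
#' Two one-sided p-values are reported; they overlap at ties, so they can
#' sum to more than 1.
#'
#' @param net `igraph` graph.
#' @param statistic a graph-level statistic: either a function
#'   `g -> numeric(1)` or one of `"density"`, `"edges"`, `"transitivity"`,
#'   `"reciprocity"`, `"char_path_length"`, `"max_eigencentrality"`,
#'   `"max_flow_betweenness"`, `"mean_flow_betweenness"`.
#' @param conditioning `"size"`, `"edges"` or `"dyad_census"`.
#' @param R number of null draws, default 1000.
#' @param seed RNG seed; the null-draw sequence is reproducible.
#' @return An object of class `cug_result`: list with `statistic_name`,
#'   `observed`, `null_draws`, `p_greater` (proportion of null >=
#'   observed), `p_less`, `conditioning`, `R`, `seed`.
#' @export
cug_test <- function(net, statistic,
                     conditioning = c("size", "edges", "dyad_census"),
                     R = 1000L, seed = 1L) {
  conditioning <- match.arg(conditioning)
  directed <- igraph::is_directed(net)
  if (conditioning == "dyad_census" && !directed)
    stop("dyad_census conditioning requires a directed network")
  if (is.character(statistic)) {
    statistic_name <- statistic
    fns <- .cug_builtins()
    if (!statistic %in% names(fns))
      stop("unknown statistic: ", statistic, "; available: ",
           paste(names(fns), collapse = ", "))
    fn <- fns[[statistic]]
  } else {
    stopifnot(is.function(statistic))
    statistic_name <- deparse(substitute(statistic))[1]
    fn <- statistic
  }
  observed <- fn(net)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  weights <- igraph::E(net)$weight %||% numeric(0)
  dyads <- if (directed) {
    dc <- igraph::dyad_census(net)
    list(mut = dc$mut, asym = dc$asym, null = dc$null)
  } else NULL
  set.seed(as.integer(seed))
  null_draws <- vapply(seq_len(R), function(r)
    fn(.cug_draw(n, directed, m, conditioning, weights, dyads)), 0)
  structure(list(
    statistic_name = statistic_name, observed = observed,
    null_draws = null_draws,
    p_greater = mean(null_draws >= observed),
    p_less = mean(null_draws <= observed),
    conditioning = conditioning, R = as.integer(R),
    seed = as.integer(seed)), class = "cug_result")
}

#' @export
print.cug_result <- function(x, ...) {
  cat(sprintf(
    "CUG test of %s (conditioning: %s, R = %d)\n", x$statistic_name,
    x$conditioning, x$R))
  cat(sprintf("  observed: %.6g\n", x$observed))
  cat(sprintf("  null mean (sd): %.6g (%.3g)\n", mean(x$null_draws),
              stats::sd(x$null_draws)))
  cat(sprintf("  Pr(null >= obs) = %.4f, Pr(null <= obs) = %.4f\n",
              x$p_greater, x$p_less))
  invisible(x)
}

#' Serialize a CUG result to JSON
#'
#' @param x a `cug_result`.
#' @param path optional file to write to.
#' @return JSON string (invisibly if written to `path`).
#' @export
cug_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cug_result"))
  j <- jsonlite::toJSON(list(
    statistic = x$statistic_name, conditioning = x$conditioning,
    R = x$R, seed = x$seed, observed = x$observed,
    p_greater = x$p_greater, p_less = x$p_less,
    null_quantiles = as.list(stats::quantile(
      x$null_draws, c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE))),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}
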