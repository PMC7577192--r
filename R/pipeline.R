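#' Configuration for the full age-stratified analysis
#'
#' Collects every analytic setting of [run_full_analysis()]. Provide either
#' `input` (path to a cohort CSV) or `spec` (a [cohort_spec()] for a
#' synthetic cohort); every random stage is seeded.
#'
#' @param input path to a cohort CSV, or `NULL`.
#' @param spec a [cohort_spec()], or `NULL`.
#' @param boundaries age stratum boundaries.
#' @param alpha significance gate for the physiological network.
#' @param epsilon_threshold arc gate for the pathological-states network.
#' @param cug_R null draws per CUG test (0 disables CUG testing).
#' @param cug_conditionings conditionings to run per network;
#'   `"dyad_census"` is applied to directed networks only.
#' @param seed master seed for generation, community detection and CUG
#'   draws.
#' @param out_dir output directory, or `NULL` for an in-memory run.
#' @param insulin_conversion passed to [assess_states()].
#' @param waist_height_ratio passed to [clean_cohort()].
#' @param low_n minimum stratum size below which networks are flagged (not
#'   skipped) in the manifest.
#' @return An object of class `metabonet_config`.
#' @export
analysis_config <- function(input = NULL, spec = NULL,
                            boundaries = c(18, 25, 35, 45, 55, 65),
                            alpha = 0.001, epsilon_threshold = 1.96,
                            cug_R = 500L,
                            cug_conditionings = c("edges"),
                            seed = 1L, out_dir = NULL,
                            insulin_conversion = 6.945,
                            waist_height_ratio = c(0.25, 1.10),
                            low_n = 30L) {
  if (is.null(input) && is.null(spec))
    stop("provide either an input path or a synthetic cohort spec")
  stopifnot(alpha > 0, epsilon_threshold > 0, cug_R >= 0)
  structure(list(
    input = input, spec = spec, boundaries = boundaries, alpha = alpha,
    epsilon_threshold = epsilon_threshold, cug_R = as.integer(cug_R),
    cug_conditionings = cug_conditionings, seed = as.integer(seed),
    out_dir = out_dir, insulin_conversion = insulin_conversion,
    waist_height_ratio = waist_height_ratio, low_n = as.integer(low_n)),
    class = "metabonet_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML may carry `input`, `spec` (path to a cohort-spec YAML),
#' and any scalar setting of [analysis_config()].
#'
#' @param path YAML file.
#' @return A `metabonet_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec)) read_cohort_spec(y$spec) else NULL
  args <- y[setdiff(names(y), "spec")]
  args$spec <- spec
  do.call(analysis_config, args)
}

# all per-network analytics for one graph
.analyze_network <- function(net, label, kind, config) {
  directed <- igraph::is_directed(net)
  centr <- list(flow_betweenness = flow_betweenness(net))
  if (directed) {
    ha <- hub_authority(net)
    centr$hub <- ha$hub
    centr$authority <- ha$authority
    centr$eigencentrality <- eigencentrality(net)
  } else {
    centr$eigencentrality <- eigencentrality(net)
  }
  comm <- if (igraph::ecount(net) > 0) {
    if (directed) spinglass_communities(net, seed = config$seed)
    else louvain_communities(net, seed = config$seed)
  } else NULL
  cug <- list()
  if (config$cug_R > 0 && igraph::ecount(net) > 0) {
    stats_to_test <- c("transitivity", "char_path_length",
                       if (directed) "reciprocity")
    conds <- config$cug_conditionings
    if (!directed) conds <- setdiff(conds, "dyad_census")
    for (cond in conds) {
      for (st in stats_to_test) {
        cug[[paste(st, cond, sep = ".")]] <-
          cug_test(net, st, conditioning = cond, R = config$cug_R,
                   seed = config$seed)
      }
    }
  }
  list(label = label, kind = kind, network = net,
       topology = topology_summary(net),
       centrality = centr,
       cliques = largest_cliques_report(net),
       communities = comm,
       cug = cug,
       low_n = FALSE)
}

#' Run the full age-stratified network analysis
#'
#' End-to-end pipeline: read (or generate) the cohort, mask implausible
#' values, derive the pathological states, then for the pooled sample and
#' each age stratum build the physiological and pathological networks and
#' characterize them (topology, centralities, largest cliques, communities,
#' CUG tests). Cohort-level outputs are the variable/state age trends and
#' metabolic syndrome prevalence by stratum. Deterministic given the
#' config's seeds.
#'
#' @param config a [analysis_config()].
#' @return A `report_bundle` list: `cohort`, `cleaning_report`, `states`,
#'   `mets` (per-stratum prevalence), `trends`, `networks` (named list of
#'   per-network analyses, names like `"physio.total"`,
#'   `"patho.25-34"`), `clique_frequency` (per network kind), `config` and
#'   `manifest`. If `config$out_dir` is set, all tables, networks (GraphML
#'   and edge-list CSV) and a manifest JSON are written there.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "metabonet_config"))
  cohort <- if (!is.null(config$input)) read_cohort(config$input)
            else generate_cohort(config$spec, seed = config$seed)
  cleaned <- clean_cohort(cohort, waist_height_ratio = config$waist_height_ratio)
  cohort <- cleaned$cohort
  states <- assess_states(cohort,
                          insulin_conversion = config$insulin_conversion)
  mets <- mets_harmonized(cohort)
  strata <- stratify_by_age(cohort, config$boundaries)
  groups <- c(list(total = cohort), strata)
  stratum_of <- cut(cohort$age, breaks = c(config$boundaries, Inf),
                    right = FALSE, labels = names(strata))

  networks <- list()
  for (lab in names(groups)) {
    sub <- groups[[lab]]
    if (nrow(sub) == 0) next
    sub_states <- states[match(sub$participant_id, cohort$participant_id), ,
                         drop = FALSE]
    phys <- build_physio_network(spearman_matrix(sub), alpha = config$alpha)
    path <- build_patho_network(sub_states,
                                threshold = config$epsilon_threshold)
    a_phys <- .analyze_network(phys, lab, "physio", config)
    a_path <- .analyze_network(path, lab, "patho", config)
    a_phys$low_n <- a_path$low_n <- nrow(sub) < config$low_n
    networks[[paste0("physio.", lab)]] <- a_phys
    networks[[paste0("patho.", lab)]] <- a_path
  }

  clique_frequency <- list(
    physio = membership_frequency(lapply(
      networks[grep("^physio\\.", names(networks))], `[[`, "cliques")),
    patho = membership_frequency(lapply(
      networks[grep("^patho\\.", names(networks))], `[[`, "cliques")))

  mets_by_stratum <- vapply(names(strata), function(lab) {
    x <- mets[stratum_of == lab]
    mean(x, na.rm = TRUE)
  }, 0)
  mets_tab <- data.frame(
    stratum = c("total", names(strata)),
    n = c(nrow(cohort), vapply(strata, nrow, 0L)),
    mets_prevalence = c(mean(mets, na.rm = TRUE), mets_by_stratum),
    stringsAsFactors = FALSE)

  trends <- trend_statistics(cohort, states, config$boundaries)

  bundle <- structure(list(
    cohort = cohort, cleaning_report = cleaned$report, states = states,
    mets = mets_tab, trends = trends, networks = networks,
    clique_frequency = clique_frequency, config = config,
    manifest = NULL), class = "report_bundle")
  bundle$manifest <- .build_manifest(bundle)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

# hash of the analytic settings; identical settings <=> identical hash
.config_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  rlang::hash(cfg)
}

.build_manifest <- function(bundle) {
  config <- bundle$config
  list(
    config_hash = .config_hash(config),
    n_participants = nrow(bundle$cohort),
    n_masked_cells = nrow(bundle$cleaning_report$masked_cells),
    networks = lapply(bundle$networks, function(a)
      list(kind = a$kind, stratum = a$label,
           n_nodes = igraph::vcount(a$network),
           n_edges = igraph::ecount(a$network),
           low_n = a$low_n)))
}

# flatten per-network analyses into tidy tables and write everything
.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, name)
  }
  topo <- do.call(rbind, lapply(bundle$networks, function(a)
    cbind(kind = a$kind, stratum = a$label, a$topology)))
  rownames(topo) <- NULL
  wr(topo, "topology.csv")

  rbind_fill <- function(dfs) {
    cols <- unique(unlist(lapply(dfs, names)))
    do.call(rbind, lapply(dfs, function(d) {
      for (cc in setdiff(cols, names(d))) d[[cc]] <- NA_real_
      d[, cols, drop = FALSE]
    }))
  }
  centr <- rbind_fill(lapply(bundle$networks, function(a) {
    nodes <- igraph::V(a$network)$name
    df <- data.frame(kind = a$kind, stratum = a$label, node = nodes,
                     stringsAsFactors = FALSE)
    for (nm in names(a$centrality)) df[[nm]] <- unname(a$centrality[[nm]])
    if (!is.null(a$communities))
      df$community <- unname(a$communities$membership[nodes])
    df
  }))
  rownames(centr) <- NULL
  wr(centr, "centrality.csv")

  cl <- do.call(rbind, lapply(bundle$networks, function(a)
    data.frame(kind = a$kind, stratum = a$label, size = a$cliques$size,
               clique = vapply(a$cliques$cliques, paste, "",
                               collapse = "+"),
               stringsAsFactors = FALSE)))
  rownames(cl) <- NULL
  wr(cl, "largest_cliques.csv")

  freq <- rbind(
    data.frame(kind = "physio",
               node = names(bundle$clique_frequency$physio),
               frequency = unname(bundle$clique_frequency$physio)),
    data.frame(kind = "patho",
               node = names(bundle$clique_frequency$patho),
               frequency = unname(bundle$clique_frequency$patho)))
  wr(freq, "clique_frequency.csv")

  wr(bundle$mets, "mets_prevalence.csv")
  wr(bundle$trends$variables, "variable_trends.csv")
  wr(bundle$trends$states, "state_trends.csv")
  wr(bundle$cleaning_report$masked_cells, "masked_cells.csv")

  for (nm in names(bundle$networks)) {
    a <- bundle$networks[[nm]]
    gml <- paste0(nm, ".graphml")
    net <- a$network
    for (attr_nm in names(a$centrality))
      net <- igraph::set_vertex_attr(net, attr_nm,
                                     value = unname(a$centrality[[attr_nm]]))
    if (!is.null(a$communities))
      net <- igraph::set_vertex_attr(
        net, "community",
        value = unname(a$communities$membership[igraph::V(net)$name]))
    igraph::write_graph(net, file.path(out_dir, gml), format = "graphml")
    files <- c(files, gml)
    edg <- paste0(nm, ".edges.csv")
    write_edge_list(a$network, file.path(out_dir, edg))
    files <- c(files, edg)
  }

  cug_flat <- list()
  for (nm in names(bundle$networks)) {
    a <- bundle$networks[[nm]]
    for (cn in names(a$cug)) {
      x <- a$cug[[cn]]
      cug_flat[[paste(nm, cn, sep = ".")]] <- list(
        statistic = x$statistic_name, conditioning = x$conditioning,
        observed = x$observed, p_greater = x$p_greater, p_less = x$p_less,
        R = x$R)
    }
  }
  jsonlite::write_json(cug_flat, file.path(out_dir, "cug_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "cug_tests.json")

  manifest <- bundle$manifest
  manifest$files <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Weighted transitivity by age group
#'
#' The per-stratum mean and standard error (over nodes) of the local
#' weighted clustering coefficient, for each network kind; the stratum
#' where each kind peaks is flagged (pooled-sample networks are reported
#' but not eligible as the peak).
#'
#' @param bundle a `report_bundle` from [run_full_analysis()].
#' @return Data frame with columns `kind`, `stratum`,
#'   `mean_weighted_transitivity`, `sem`, `n_nodes`, `is_peak`.
#' @export
transitivity_by_age <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  rows <- lapply(bundle$networks, function(a) {
    wc <- if (igraph::ecount(a$network) > 0)
      weighted_clustering(a$network,
                          if (igraph::is_directed(a$network))
                            "directed_weighted" else "barrat_local")
    else list(global = NA_real_, sem = NA_real_, local = numeric(0))
    data.frame(kind = a$kind, stratum = a$label,
               mean_weighted_transitivity = wc$global, sem = wc$sem,
               n_nodes = sum(!is.na(wc$local)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$is_peak <- FALSE
  for (k in unique(out$kind)) {
    age_rows <- which(out$kind == k & out$stratum != "total" &
                        !is.na(out$mean_weighted_transitivity))
    if (length(age_rows) > 0) {
      peak <- age_rows[which.max(out$mean_weighted_transitivity[age_rows])]
      out$is_peak[peak] <- TRUE
    }
  }
  out
}
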