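# Configuration-driven end-to-end runner: grouping, equating, network
# estimation, null validation, bootstrap comparison, unique-response test,
# and table/graph exports.

#' Default pipeline configuration
#'
#' @param seed Master integer seed (mandatory).
#' @param ... Overrides of any default field: `synthetic` (logical; use the
#'   built-in study generator), `grouping` (score column to median-split
#'   on), `min_producers`, `min_per_group`, `n_sims` (null ensemble),
#'   `n_boot`, `proportions`, `restarts`, `n_ref`, `out_dir`, and for real
#'   data the input paths `responses`, `scores`, `lemma_map`, `lexicon`.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(seed, ...) {
  cfg <- utils::modifyList(
    list(seed = seed, synthetic = TRUE, synthetic_args = list(),
         grouping = "odt", min_producers = 2, min_per_group = 2,
         n_sims = 1000, n_boot = 1000,
         proportions = seq(0.5, 0.9, by = 0.1),
         restarts = 10, n_ref = 100,
         responses = NULL, scores = NULL, lemma_map = NULL, lexicon = NULL,
         out_dir = "fluencynets-run"),
    list(...))
  if (is.null(cfg$seed)) stop_stage("config", "a seed is mandatory")
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path Configuration file; fields as in [run_config()].
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_stage("config", "config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("responses", "scores", "lemma_map", "lexicon")) {
    if (!is.null(raw[[f]]) && !file.exists(raw[[f]])) {
      stop_stage("config", "referenced path does not exist: ", raw[[f]])
    }
  }
  do.call(run_config, raw)
}

#' Run the full group-based semantic network pipeline
#'
#' Stages: (1) score table and median-split grouping; (2) response
#' preprocessing into the full-universe incidence matrix; (3) per-group
#' matrices and cross-group equating; (4) cosine/TMFG/binarized network per
#' group; (5) network measures, Erdos-Renyi nulls and Z-tests; (6) graded
#' bootstrap partial-network t-tests; (7) unique-response McNemar test.
#' Writes `table1.csv` (index correlations) through `table6.csv`
#' (bootstrap comparisons), `mcnemar.csv`, graph exports (edge-list CSV and
#' GraphML per group), the equated incidence matrices, a ground-truth JSON
#' (for synthetic runs), a run log, and returns everything invisibly.
#' Outputs contain no timestamps, so identical configurations produce
#' byte-identical bundles.
#'
#' @param config A `run_config` list (or path to a YAML/JSON config file).
#' @return (Invisibly) list with the grouped matrices, graphs, measure
#'   tables, null distributions, bootstrap results and McNemar results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
    invisible(NULL)
  }
  log_add("fluencynets run, seed=", config$seed)

  # -- stage 1: inputs and grouping ----------------------------------------
  if (isTRUE(config$synthetic)) {
    study <- do.call(simulate_study,
                     c(list(seed = config$seed), config$synthetic_args))
    records <- study$records
    scores <- study$scores
    log_add("synthetic study: ", nrow(scores), " participants, ",
            study$spec$true_spec$n_words, " word lexicon")
  } else {
    if (is.null(config$responses) || is.null(config$scores)) {
      stop_stage("config", "non-synthetic runs need 'responses' and 'scores'")
    }
    records <- load_responses(config$responses)
    scores <- utils::read.csv(config$scores, stringsAsFactors = FALSE)
    study <- NULL
  }
  if (!config$grouping %in% names(scores)) {
    stop_stage("config", "grouping variable '", config$grouping,
               "' not found in the scores table")
  }
  split <- median_split(scores, variable = config$grouping)
  log_add("median split on '", config$grouping, "': threshold = ",
          signif(attr(split, "threshold"), 6))

  # -- stage 2/3: incidence matrix, group matrices, equating ---------------
  lemma <- if (!is.null(config$lemma_map))
    utils::read.csv(config$lemma_map, stringsAsFactors = FALSE) else NULL
  lexicon <- if (!is.null(config$lexicon)) readLines(config$lexicon) else NULL
  mat <- preprocess_responses(records, lemma_map = lemma,
                              category_lexicon = lexicon,
                              min_producers = config$min_producers)
  log_add("incidence matrix: ", nrow(mat), " participants x ", ncol(mat),
          " tokens; attrition: ",
          paste(names(attr(mat, "attrition")), attr(mat, "attrition"),
                sep = "=", collapse = ", "))
  ids_low <- split$participant[split$group == "low"]
  ids_high <- split$participant[split$group == "high"]
  mat_low <- mat[intersect(rownames(mat), ids_low), , drop = FALSE]
  mat_high <- mat[intersect(rownames(mat), ids_high), , drop = FALSE]
  eq <- equate_groups(mat_low, mat_high, min_per_group = config$min_per_group)
  log_add("equated word set: ", length(eq$words), " tokens")

  # -- stage 4: networks ----------------------------------------------------
  g_low <- estimate_network(eq$low)
  g_high <- estimate_network(eq$high)

  # -- stage 5: measures, nulls, z-tests -----------------------------------
  n_nodes <- length(eq$words)
  n_edges <- igraph::ecount(g_low)
  null <- random_network_null(n_nodes, n_edges, n_sims = config$n_sims,
                              seed = derive_seed(config$seed, 11),
                              restarts = config$restarts,
                              n_ref = config$n_ref)
  meas <- function(g, label, s_seed) {
    set.seed(s_seed)
    m <- network_measures(g, restarts = config$restarts,
                          n_ref = config$n_ref, ref_stats = null$reference)
    cbind(network = label, m)
  }
  measures <- rbind(meas(g_low, "low", derive_seed(config$seed, 12)),
                    meas(g_high, "high", derive_seed(config$seed, 13)))
  ztab <- do.call(rbind, lapply(c("cc", "aspl", "q", "s"), function(msr) {
    do.call(rbind, lapply(c("low", "high"), function(grp) {
      emp <- measures[measures$network == grp, msr]
      zt <- z_test(emp, null, measure = msr)
      data.frame(measure = msr, network = grp, empirical = emp,
                 null_mean = null$mean[[msr]], null_sd = null$sd[[msr]],
                 z = zt$z, p = zt$p)
    }))
  }))

  # -- stage 6: bootstrap comparison ---------------------------------------
  boot <- bootstrap_partial(eq$low, eq$high,
                            proportions = config$proportions,
                            n_boot = config$n_boot,
                            seed = derive_seed(config$seed, 14),
                            restarts = config$restarts,
                            n_ref = config$n_ref)

  # -- stage 7: McNemar on the full token universe -------------------------
  mc <- mcnemar_unique(mat_low, mat_high)

  # -- reports --------------------------------------------------------------
  out <- function(f) file.path(config$out_dir, f)
  cor_vars <- intersect(c("flexibility", "fluency", "creativity_sum", "odt"),
                        names(scores))
  if (length(cor_vars) >= 2) {
    ct <- correlate_indices(scores, vars = cor_vars,
                            log_vars = setdiff(cor_vars, "odt"))
    utils::write.csv(round(ct$rho, 3), out("table1.csv"))
  }
  covars <- intersect(c("wpm", "voc", "svf", "spm", "odt"), names(scores))
  t2 <- do.call(rbind, lapply(covars, function(v) {
    x <- scores[[v]][match(ids_high, scores$participant)]
    y <- scores[[v]][match(ids_low, scores$participant)]
    cmp <- compare_groups(x, y)   # high minus low
    data.frame(variable = v,
               mean_low = mean(y), sd_low = stats::sd(y),
               mean_high = mean(x), sd_high = stats::sd(x),
               t = cmp$t, p = cmp$p, d = cmp$d)
  }))
  utils::write.csv(t2, out("table2.csv"), row.names = FALSE)
  utils::write.csv(ztab, out("table3.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(boot), out("table4.csv"), row.names = FALSE)
  utils::write.csv(measures, out("table5.csv"), row.names = FALSE)
  mc_df <- data.frame(n_total = mc$counts$n_total, both = mc$counts$a,
                      high_only = mc$counts$b, low_only = mc$counts$c,
                      n_high = mc$n_high, n_low = mc$n_low,
                      prop_high = mc$prop_high, prop_low = mc$prop_low,
                      chi2 = mc$chi2, p = mc$p, phi = mc$phi)
  utils::write.csv(mc_df, out("table6.csv"), row.names = FALSE)
  for (grp in c("low", "high")) {
    g <- if (grp == "low") g_low else g_high
    export_graph(g, out(paste0("network_", grp, ".csv")), "edgelist")
    export_graph(g, out(paste0("network_", grp, ".graphml")), "graphml")
  }
  write_incidence(eq$low, out("incidence_low.csv"))
  write_incidence(eq$high, out("incidence_high.csv"))
  if (!is.null(study)) {
    jsonlite::write_json(
      list(spec = study$spec,
           planted_partition = study$true_network$partition,
           groups = as.list(study$groups)),
      out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  log_add("null draws disconnected: ", null$n_disconnected, "/",
          null$n_sims)
  log_add("bootstrap realizations: ", config$n_boot, " x ",
          length(config$proportions), " proportions")
  writeLines(log_lines, out("run.log"))

  invisible(list(config = config, study = study, split = split,
                 matrix_full = mat, equated = eq,
                 graphs = list(low = g_low, high = g_high),
                 measures = measures, null = null, z_tests = ztab,
                 bootstrap = boot, mcnemar = mc))
}

#' Export a semantic graph
#'
#' @param g igraph object with named vertices.
#' @param path Output file.
#' @param format `"edgelist"` (two-column CSV of token pairs) or
#'   `"graphml"`.
#' @return The path, invisibly.
#' @export
export_graph <- function(g, path, format = c("edgelist", "graphml")) {
  if (igraph::vcount(g) == 0) stop_stage("export_graph", "empty graph")
  format <- tryCatch(match.arg(format),
                     error = function(e)
                       stop_stage("export_graph",
                                  "unknown format; supported: edgelist, graphml"))
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g)
    df <- data.frame(token_a = el[, 1], token_b = el[, 2],
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read back an exported semantic graph
#'
#' @param path File written by [export_graph()].
#' @param format `"edgelist"` or `"graphml"`.
#' @return igraph object.
#' @export
import_graph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    igraph::graph_from_edgelist(as.matrix(df[, 1:2]), directed = FALSE)
  } else {
    igraph::read_graph(path, format = "graphml")
  }
}
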