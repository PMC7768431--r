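# Validation machinery: Erdos-Renyi null distributions with Z-tests, graded
# bootstrap partial-network group comparisons, and the unique-response
# McNemar test.

#' Erdos-Renyi null distributions of the network measures
#'
#' Simulates `n_sims` G(n, m) random graphs with the same node and edge
#' counts as an empirical network and computes CC, ASPL, Q and S for each.
#' The small-world reference terms (CC_rand, ASPL_rand) are computed once
#' from a separate ensemble of `n_ref` matched G(n, m) draws and shared by
#' all simulations, since they depend only on (n, m). Disconnected draws
#' have ASPL computed on the largest component and are counted.
#'
#' @param n_nodes,n_edges Matched size of the simulated graphs.
#' @param n_sims Number of simulated graphs (default 1000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param restarts Louvain restarts per graph.
#' @param n_ref Size of the small-world reference ensemble.
#' @return Object of class `null_distribution`: a list with `values` (data
#'   frame of per-simulation cc, aspl, q, s), `mean` and `sd` (named vectors),
#'   `n_disconnected`, and the simulation parameters.
#' @export
random_network_null <- function(n_nodes, n_edges, n_sims = 1000, seed,
                                restarts = 10, n_ref = 100) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop_stage("random_network_null", "more edges than node pairs")
  }
  if (n_sims < 100) stop_stage("random_network_null", "n_sims must be >= 100")
  set.seed(seed)
  ref <- er_reference_stats(n_nodes, n_edges, n_ref = n_ref)
  cc <- numeric(n_sims); ap <- numeric(n_sims)
  q <- numeric(n_sims); s <- numeric(n_sims)
  n_disc <- 0L
  for (i in seq_len(n_sims)) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    if (!igraph::is_connected(g)) n_disc <- n_disc + 1L
    cc[i] <- clustering_coefficient(g)
    ap[i] <- suppressWarnings(aspl(g))
    q[i] <- modularity_louvain(g, restarts = restarts)$q
    s[i] <- (cc[i] / ref$cc) / (ap[i] / ref$aspl)
  }
  if (n_disc > n_sims / 100) {
    warning(sprintf("%d of %d null draws were disconnected", n_disc, n_sims))
  }
  values <- data.frame(cc = cc, aspl = ap, q = q, s = s)
  structure(list(values = values,
                 mean = vapply(values, mean, numeric(1)),
                 sd = vapply(values, stats::sd, numeric(1)),
                 n_disconnected = n_disc,
                 n_nodes = n_nodes, n_edges = n_edges, n_sims = n_sims,
                 reference = ref, seed = seed),
            class = "null_distribution")
}

#' One-sample Z-test against a simulated null distribution
#'
#' `z = (empirical - mean_null) / sd_null`, two-sided normal p-value.
#'
#' @param empirical Observed measure value.
#' @param null Either a `null_distribution` (with `measure` naming the
#'   column) or a list with `mean` and `sd` scalars.
#' @param measure Measure name when `null` is a `null_distribution`.
#' @return List with `z` and `p`.
#' @export
z_test <- function(empirical, null, measure = NULL) {
  if (inherits(null, "null_distribution")) {
    if (is.null(measure)) stop_stage("z_test", "measure name required")
    mu <- null$mean[[measure]]; sigma <- null$sd[[measure]]
  } else {
    mu <- null$mean; sigma <- null$sd
  }
  if (!is.finite(sigma) || sigma <= 0) {
    stop_stage("z_test", "null standard deviation must be positive")
  }
  z <- (empirical - mu) / sigma
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Graded bootstrap partial-network group comparison
#'
#' For each node-retention proportion, draws `n_boot` random node subsets
#' (without replacement, size `round(p * n)` with half rounded away from
#' zero). Each subset is applied to *both* equated group matrices so the
#' paired partial networks share nodes; each partial network is then
#' re-estimated from scratch (cosine similarity, TMFG, binarization) and its
#' measures computed. Per (proportion, measure), the n_boot low-group and
#' high-group values are compared with a pooled-variance two-sample t-test
#' (df = 2 n_boot - 2) and Cohen's d; the statistic is low minus high, so a
#' positive t means the low group scores higher.
#'
#' Per-realization random substreams are derived from the master seed by
#' counter, so increasing `n_boot` extends, rather than reshuffles, earlier
#' draws. The small-world reference terms are cached per subset size.
#'
#' @param mat_low,mat_high Equated incidence matrices (identical columns).
#' @param proportions Node-retention proportions (default 0.5 to 0.9).
#' @param n_boot Realizations per proportion (default 1000).
#' @param seed Master integer seed.
#' @param measures Which measures to compute (`"cc"`, `"aspl"`, `"q"`, `"s"`).
#' @param restarts Louvain restarts.
#' @param n_ref Reference ensemble size for S (cached per subset size).
#' @return Object of class `bootstrap_result`: a data frame with one row per
#'   (proportion, measure) holding group means/sds, `t`, `df`, `p`, `d`; the
#'   per-realization values are kept in the `samples` attribute, and
#'   realizations where all-zero columns had to be dropped are counted in
#'   the `n_dropped_columns` attribute.
#' @export
bootstrap_partial <- function(mat_low, mat_high,
                              proportions = seq(0.5, 0.9, by = 0.1),
                              n_boot = 1000, seed,
                              measures = c("cc", "aspl", "q", "s"),
                              restarts = 10, n_ref = 100) {
  if (!identical(colnames(mat_low), colnames(mat_high))) {
    stop_stage("bootstrap", "matrices must share identical word columns; ",
               "run equate_groups() first")
  }
  measures <- match.arg(measures, several.ok = TRUE)
  n <- ncol(mat_low)
  sizes <- round_half_up(proportions * n)
  if (any(sizes < 4)) {
    stop_stage("bootstrap", "a proportion yields fewer than 4 nodes")
  }

  # reference stats for S, cached per subset size, seeds derived per size
  ref_cache <- new.env(parent = emptyenv())
  get_ref <- function(k) {
    key <- as.character(k)
    if (is.null(ref_cache[[key]])) {
      ref_cache[[key]] <- er_reference_stats(
        k, 3 * k - 6, n_ref = n_ref, seed = derive_seed(seed, 1e6 + k))
    }
    ref_cache[[key]]
  }

  if ("s" %in% measures) for (k in unique(sizes)) get_ref(k)

  # both group networks of one realization share `louvain_seed`, so paired
  # sides see identical community-detection noise and identical matrices
  # give exactly identical measures
  one_side <- function(mat, keep, ref, louvain_seed) {
    g <- estimate_network(mat[, keep, drop = FALSE])
    cc_g <- clustering_coefficient(g)
    ap_g <- aspl(g)
    out <- c(
      cc = cc_g, aspl = ap_g,
      q = if ("q" %in% measures)
        modularity_louvain(g, restarts = restarts, seed = louvain_seed)$q
      else NA_real_,
      s = if ("s" %in% measures)
        (cc_g / ref$cc) / (ap_g / ref$aspl) else NA_real_)
    out[measures]
  }

  samples <- list()
  rows <- list()
  n_dropped <- 0L
  for (ip in seq_along(proportions)) {
    p <- proportions[ip]
    k <- sizes[ip]
    low_vals <- matrix(NA_real_, n_boot, length(measures),
                       dimnames = list(NULL, measures))
    high_vals <- low_vals
    for (b in seq_len(n_boot)) {
      real_seed <- derive_seed(seed, round(1000 * p) * 1e5 + b)
      set.seed(real_seed)
      keep <- sort(sample.int(n, k))
      # equating guarantees column sums >= 2, but guard generic inputs
      cs_low <- colSums(mat_low[, keep, drop = FALSE])
      cs_high <- colSums(mat_high[, keep, drop = FALSE])
      bad <- cs_low == 0 | cs_high == 0
      if (any(bad)) {
        n_dropped <- n_dropped + sum(bad)
        keep <- keep[!bad]
        if (length(keep) < 4) next
      }
      ref <- if ("s" %in% measures) get_ref(length(keep)) else NULL
      lseed <- derive_seed(real_seed, 1)
      low_vals[b, ] <- one_side(mat_low, keep, ref, lseed)
      high_vals[b, ] <- one_side(mat_high, keep, ref, lseed)
    }
    for (msr in measures) {
      ok <- stats::complete.cases(low_vals[, msr], high_vals[, msr])
      cmp <- compare_groups(low_vals[ok, msr], high_vals[ok, msr])
      rows[[length(rows) + 1]] <- data.frame(
        proportion = p, measure = msr,
        mean_low = cmp$mean_x, sd_low = stats::sd(low_vals[ok, msr]),
        mean_high = cmp$mean_y, sd_high = stats::sd(high_vals[ok, msr]),
        t = cmp$t, df = cmp$df, p = cmp$p, d = cmp$d)
    }
    samples[[as.character(p)]] <- list(low = low_vals, high = high_vals)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, samples = samples, n_dropped_columns = n_dropped,
            seed = seed, class = c("bootstrap_result", "data.frame"))
}

#' McNemar test on unique-response production
#'
#' Over the full (un-equated) token universe, classifies each token by
#' whether it was produced by at least one participant in each group:
#' `a` in both, `b` high-only, `c` low-only. The continuity-corrected
#' McNemar statistic is `chi2 = (|b - c| - 1)^2 / (b + c)` with 1 df, and
#' the effect size is `phi = sqrt(chi2 / N)` with `N = a + b + c`.
#'
#' @param mat_low,mat_high Incidence matrices over the same token universe
#'   (columns are aligned on their union; missing columns count as zero).
#' @return List with `counts` (`n_total`, `a`, `b`, `c`), group unique-token
#'   totals and proportions, `chi2`, `p`, `phi`. With no discordant tokens
#'   (`b + c = 0`) the statistic is undefined and `NA` is returned with a
#'   message in `note`.
#' @export
mcnemar_unique <- function(mat_low, mat_high) {
  universe <- sort(union(colnames(mat_low), colnames(mat_high)))
  produced <- function(m) {
    out <- stats::setNames(rep(FALSE, length(universe)), universe)
    out[colnames(m)] <- colSums(m) >= 1
    out
  }
  in_low <- produced(mat_low)
  in_high <- produced(mat_high)
  present <- in_low | in_high
  a <- sum(in_low & in_high)
  b <- sum(in_high & !in_low)
  c <- sum(in_low & !in_high)
  n_total <- sum(present)
  counts <- list(n_total = n_total, a = a, b = b, c = c)
  res <- list(counts = counts,
              n_high = a + b, n_low = a + c,
              prop_high = (a + b) / n_total, prop_low = (a + c) / n_total)
  if (b + c == 0) {
    res$chi2 <- NA_real_; res$p <- NA_real_; res$phi <- NA_real_
    res$note <- "no discordant tokens; McNemar statistic undefined"
    return(res)
  }
  chi2 <- (abs(b - c) - 1)^2 / (b + c)
  res$chi2 <- chi2
  res$p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  res$phi <- sqrt(chi2 / n_total)
  res
}
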