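# Synthetic two-group fluency studies with known ground truth: censored
# random walks over a planted-community semantic network, plus correlated
# behavioral scores. These defaults emulate the study conditions the
# pipeline was designed for: 58 participants in two groups of 29, about ten
# animal-category responses each, and a produced-token universe of roughly
# 120-140 words.

#' Generate a planted-partition "true" semantic network
#'
#' Draws a stochastic block model graph with `n_communities` equally sized
#' communities, within-community edge probability `p_in` and between-
#' community probability `p_out`, regenerating until the graph is connected.
#'
#' @param n_words Number of words (nodes); default 140.
#' @param n_communities Number of planted communities; default 7.
#' @param p_in,p_out Edge probabilities (0 <= p_out < p_in <= 1).
#' @param seed Integer seed.
#' @param max_tries Regeneration attempts before giving up (default 100).
#' @return List with `graph` (igraph, nodes named `w001`, ...), `partition`
#'   (integer vector of planted communities) and the generating parameters.
#' @export
make_true_network <- function(n_words = 140, n_communities = 7,
                              p_in = 0.25, p_out = 0.02, seed,
                              max_tries = 100) {
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop_stage("make_true_network", "need 0 <= p_out <= p_in <= 1")
  }
  if (n_words %% n_communities != 0) {
    stop_stage("make_true_network",
               "n_words must be divisible by n_communities")
  }
  set.seed(seed)
  sizes <- rep(n_words / n_communities, n_communities)
  pref <- matrix(p_out, n_communities, n_communities)
  diag(pref) <- p_in
  g <- NULL
  for (i in seq_len(max_tries)) {
    cand <- igraph::sample_sbm(n_words, pref.matrix = pref,
                               block.sizes = sizes)
    if (igraph::is_connected(cand)) { g <- cand; break }
  }
  if (is.null(g)) {
    stop_stage("make_true_network",
               "no connected graph in ", max_tries,
               " attempts; raise p_in/p_out")
  }
  igraph::V(g)$name <- sprintf("w%03d", seq_len(n_words))
  list(graph = g, partition = rep(seq_len(n_communities), times = sizes),
       n_words = n_words, n_communities = n_communities,
       p_in = p_in, p_out = p_out, seed = seed)
}

#' Simulate fluency lists by censored random walks
#'
#' Each participant performs a random walk on the true network: the start
#' node is uniform; at every step, with probability `jump_prob` the walker
#' teleports to a uniform random node, otherwise it moves to a uniform
#' random neighbour. A word is emitted the first time it is visited
#' (censoring), so lists contain no repetitions. The walk stops once the
#' participant's drawn response count is emitted. Response counts follow a
#' shifted Poisson, `3 + Poisson(mean_responses - 3)`, clipped to
#' `[3, n_words]`.
#'
#' @param g Connected igraph with named vertices (see [make_true_network()]).
#' @param n_participants Number of participants (default 29).
#' @param mean_responses Mean list length (default 10, the one-minute
#'   animal-fluency scale).
#' @param jump_prob Teleport probability per step; operationalizes
#'   flexibility (higher values blur community structure).
#' @param seed Integer seed.
#' @param id_prefix Participant id prefix.
#' @return Data frame with columns `participant`, `response`, `order`.
#' @export
simulate_fluency <- function(g, n_participants = 29, mean_responses = 10,
                             jump_prob = 0.2, seed, id_prefix = "P") {
  stopifnot(jump_prob >= 0, jump_prob <= 1, n_participants >= 2)
  if (!igraph::is_connected(g)) {
    stop_stage("simulate_fluency", "true network must be connected")
  }
  set.seed(seed)
  n <- igraph::vcount(g)
  words <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  target <- 3 + stats::rpois(n_participants, max(mean_responses - 3, 0))
  capped <- target > n
  if (any(capped)) {
    warning(sum(capped), " requested list length(s) exceeded n_words; capped")
    target[capped] <- n
  }
  target[target < 3] <- 3L

  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    visited <- logical(n)
    emitted <- integer(target[p])
    cur <- sample.int(n, 1)
    count <- 0L
    steps <- 0L
    while (count < target[p] && steps < 100000L) {
      steps <- steps + 1L
      if (!visited[cur]) {
        count <- count + 1L
        visited[cur] <- TRUE
        emitted[count] <- cur
      }
      cur <- if (stats::runif(1) < jump_prob || length(adj[[cur]]) == 0) {
        sample.int(n, 1)
      } else {
        nb <- adj[[cur]]
        nb[sample.int(length(nb), 1)]
      }
    }
    out[[p]] <- data.frame(
      participant = sprintf("%s%02d", id_prefix, p),
      response = words[emitted[seq_len(count)]],
      order = seq_len(count), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a complete two-group fluency study
#'
#' Builds a planted-community true network, simulates a low- and a
#' high-flexibility group of participants by censored random walks (the
#' groups differ only in their teleport probability), and attaches a
#' behavioral score table constructed so that a median split on the
#' grouping score (`odt`) exactly recovers the generating groups: low-group
#' scores are drawn from U(3, 5) and high-group scores from U(6, 8). AUT
#' component indices (`fluency`, `flexibility`, `creativity_sum`) are
#' derived monotonically from the grouping score with noise, and the
#' non-grouping covariates (`wpm`, `voc`, `spm`) are drawn group-
#' independently, so their group contrasts are null by construction. `svf`
#' is the participant's actual list length.
#'
#' @param seed Master integer seed; all substreams derive from it.
#' @param n_per_group Participants per group (default 29).
#' @param jump_low,jump_high Teleport probabilities of the two groups.
#' @param true_spec Optional list of overrides passed to
#'   [make_true_network()] (`n_words`, `n_communities`, `p_in`, `p_out`).
#' @param mean_responses Mean fluency list length (default 10).
#' @return List of class `synthetic_study` with `records` (long-format
#'   fluency data for both groups), `scores` (per-participant behavioral
#'   table), `groups` (generating group labels), `true_network`, and `spec`
#'   (all parameters and derived seeds).
#' @export
simulate_study <- function(seed, n_per_group = 29,
                           jump_low = 0.05, jump_high = 0.4,
                           true_spec = list(), mean_responses = 10) {
  ts <- utils::modifyList(
    list(n_words = 140, n_communities = 7, p_in = 0.25, p_out = 0.02),
    true_spec)
  seeds <- c(net = derive_seed(seed, 1), low = derive_seed(seed, 2),
             high = derive_seed(seed, 3), scores = derive_seed(seed, 4))
  net <- make_true_network(ts$n_words, ts$n_communities, ts$p_in, ts$p_out,
                           seed = seeds[["net"]])
  rec_low <- simulate_fluency(net$graph, n_per_group, mean_responses,
                              jump_low, seed = seeds[["low"]],
                              id_prefix = "L")
  rec_high <- simulate_fluency(net$graph, n_per_group, mean_responses,
                               jump_high, seed = seeds[["high"]],
                               id_prefix = "H")
  records <- rbind(rec_low, rec_high)

  set.seed(seeds[["scores"]])
  ids <- c(unique(rec_low$participant), unique(rec_high$participant))
  group <- rep(c("low", "high"), each = n_per_group)
  odt <- c(stats::runif(n_per_group, 3, 5), stats::runif(n_per_group, 6, 8))
  flexibility <- pmax(1L, round(odt * 0.7 + stats::rnorm(2 * n_per_group, 0, 0.4)))
  creativity_mean <- pmin(pmax(odt - flexibility, 1), 5)
  fluency <- pmax(flexibility,
                  stats::rpois(2 * n_per_group, lambda = 2 + odt))
  svf <- as.integer(table(factor(records$participant, levels = ids)))
  scores <- data.frame(
    participant = ids,
    group_true = group,
    odt = odt,
    flexibility = flexibility,
    fluency = fluency,
    creativity_sum = creativity_mean * fluency,
    wpm = stats::rnorm(2 * n_per_group, 10.8, 1.8),
    voc = round(pmin(stats::rnorm(2 * n_per_group, 13.1, 1.3), 13 + 2)),
    spm = round(stats::rnorm(2 * n_per_group, 39.5, 6)),
    svf = svf,
    stringsAsFactors = FALSE)

  structure(list(records = records, scores = scores,
                 groups = stats::setNames(group, ids),
                 true_network = net,
                 spec = list(seed = seed, seeds = as.list(seeds),
                             n_per_group = n_per_group,
                             jump_low = jump_low, jump_high = jump_high,
                             mean_responses = mean_responses,
                             true_spec = ts)),
            class = "synthetic_study")
}
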