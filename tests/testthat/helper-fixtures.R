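# Shared fixtures and independent oracles for the test suite.

make_records <- function(participant, response, order) {
  data.frame(participant = participant, response = response,
             order = order, stringsAsFactors = FALSE)
}

write_response_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("participant,response,order", lines), f)
  f
}

# random binary incidence matrix with named rows/columns
random_incidence <- function(n_part, n_words, p, seed) {
  set.seed(seed)
  m <- matrix(rbinom(n_part * n_words, 1, p), n_part, n_words,
              dimnames = list(sprintf("P%02d", seq_len(n_part)),
                              sprintf("w%02d", seq_len(n_words))))
  storage.mode(m) <- "integer"
  m
}

# independent double-loop cosine oracle
brute_cosine <- function(mat) {
  n <- ncol(mat)
  out <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      out[a, b] <- sum(mat[, a] * mat[, b]) /
        (sqrt(sum(mat[, a]^2)) * sqrt(sum(mat[, b]^2)))
    }
  }
  out
}

# random symmetric similarity matrix with unit diagonal
random_sim <- function(n, seed) {
  set.seed(seed)
  s <- matrix(runif(n * n), n, n)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- list(sprintf("t%02d", seq_len(n)), sprintf("t%02d", seq_len(n)))
  s
}

# random planar triangulation built by the same face-insertion scheme but
# with uniformly random seed clique and (node, face) choices: a baseline the
# greedy TMFG should dominate in retained weight
random_triangulation_weight <- function(sim, seed) {
  set.seed(seed)
  n <- nrow(sim)
  w <- sim; diag(w) <- 0
  seed4 <- sample.int(n, 4)
  total <- sum(w[seed4, seed4]) / 2
  faces <- t(utils::combn(seed4, 3))
  inserted <- logical(n); inserted[seed4] <- TRUE
  while (any(!inserted)) {
    rem <- which(!inserted)
    v <- rem[sample.int(length(rem), 1)]
    f <- sample.int(nrow(faces), 1)
    tri <- faces[f, ]
    total <- total + sum(w[v, tri])
    faces <- rbind(faces[-f, , drop = FALSE],
                   c(v, tri[1], tri[2]), c(v, tri[2], tri[3]),
                   c(v, tri[1], tri[3]))
    inserted[v] <- TRUE
  }
  total
}

# planarity oracle via an external graph library
is_planar <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  f <- tempfile()
  writeLines(paste(el[, 1], el[, 2]), f)
  code <- paste0(
    "import sys, networkx as nx; ",
    "g = nx.read_edgelist(sys.argv[1]); ",
    "print(nx.check_planarity(g)[0])")
  out <- system2("python", c("-c", shQuote(code), f), stdout = TRUE)
  identical(tail(out, 1), "True")
}

# definitional Newman modularity, written independently of the package
oracle_modularity <- function(g, membership) {
  m <- igraph::ecount(g)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(a)
  q <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (membership[i] == membership[j]) {
        q <- q + (a[i, j] - deg[i] * deg[j] / (2 * m)) / (2 * m)
      }
    }
  }
  q
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0)
  out
}

# simulate a two-group study and return equated + full group matrices
study_matrices <- function(seed, jump_low = 0.05, jump_high = 0.4, ...) {
  s <- simulate_study(seed = seed, jump_low = jump_low,
                      jump_high = jump_high, ...)
  mat <- preprocess_responses(s$records, min_producers = 2)
  sp <- median_split(s$scores, "odt")
  ml <- mat[intersect(rownames(mat), sp$participant[sp$group == "low"]), ,
            drop = FALSE]
  mh <- mat[intersect(rownames(mat), sp$participant[sp$group == "high"]), ,
            drop = FALSE]
  list(study = s, full_low = ml, full_high = mh,
       equated = equate_groups(ml, mh))
}

# incidence matrices realizing given both/high-only/low-only token counts
mcnemar_matrices <- function(a, b, c) {
  n <- a + b + c
  words <- sprintf("w%03d", seq_len(n))
  low <- matrix(0L, 2, n, dimnames = list(c("L1", "L2"), words))
  high <- matrix(0L, 2, n, dimnames = list(c("H1", "H2"), words))
  low[1, seq_len(a + c)] <- 1L                  # both + low-only
  high[1, c(seq_len(a), a + c + seq_len(b))] <- 1L  # both + high-only
  list(low = low, high = high)
}
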