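# Alternative Uses Task scoring, inter-rater reliability, index correlations,
# median-split grouping and group-level t-tests.

#' Score one participant's Alternative Uses Task ideas
#'
#' Each idea carries two raters' creativity ratings (1-5) and a category
#' label from a predefined list. Idea-level creativity is the mean of the two
#' raters. The participant-level scores are: `fluency` (number of
#' non-redundant ideas), `flexibility` (number of distinct categories),
#' `creativity_sum` (sum of idea-level creativity), `creativity_mean`
#' (creativity_sum / fluency) and the overall divergent thinking index
#' `odt = creativity_mean + flexibility`.
#'
#' @param ideas Data frame with columns `rater1`, `rater2` (numeric, 1-5) and
#'   `category` (character); one row per non-redundant idea. Zero rows are
#'   allowed and yield an all-zero score with a warning.
#' @return A one-row data frame with columns `fluency`, `flexibility`,
#'   `creativity_sum`, `creativity_mean`, `odt`.
#' @examples
#' score_aut(data.frame(rater1 = c(3, 4), rater2 = c(5, 4),
#'                      category = c("tool", "toy")))
#' @export
score_aut <- function(ideas) {
  if (nrow(ideas) == 0) {
    warning("no ideas: creativity_mean undefined, ODT set to 0")
    return(data.frame(fluency = 0L, flexibility = 0L, creativity_sum = 0,
                      creativity_mean = NA_real_, odt = 0))
  }
  r1 <- as.numeric(ideas$rater1)
  r2 <- as.numeric(ideas$rater2)
  if (any(r1 < 1 | r1 > 5 | r2 < 1 | r2 > 5)) {
    stop_stage("score_aut", "creativity ratings must lie in [1, 5]")
  }
  idea_creativity <- (r1 + r2) / 2
  fluency <- nrow(ideas)
  flexibility <- length(unique(as.character(ideas$category)))
  creativity_sum <- sum(idea_creativity)
  creativity_mean <- creativity_sum / fluency
  data.frame(fluency = as.integer(fluency),
             flexibility = as.integer(flexibility),
             creativity_sum = creativity_sum,
             creativity_mean = creativity_mean,
             odt = creativity_mean + flexibility)
}

#' Score a table of AUT ideas for many participants
#'
#' @param records Data frame with columns `participant`, `rater1`, `rater2`,
#'   `category`.
#' @return Data frame with one row per participant.
#' @export
score_aut_all <- function(records) {
  ids <- sort(unique(as.character(records$participant)))
  out <- do.call(rbind, lapply(ids, function(p) {
    score_aut(records[records$participant == p, , drop = FALSE])
  }))
  cbind(data.frame(participant = ids, stringsAsFactors = FALSE), out)
}

#' Two-way consistency intraclass correlation for two raters
#'
#' Computes the consistency-type ICC from the two-way ANOVA mean squares
#' (items crossed with raters): `ICC(C,1) = (MS_R - MS_E) / (MS_R + (k-1)
#' MS_E)` for a single rating and `ICC(C,k) = (MS_R - MS_E) / MS_R` for the
#' average of the k raters. Consistency ICC ignores additive rater shifts.
#'
#' @param rater1,rater2 Equal-length numeric vectors of ratings, one element
#'   per rated item; at least 3 items.
#' @return A list with elements `single` and `average`. With zero between-item
#'   variance both are `NaN` (warning).
#' @export
icc_consistency <- function(rater1, rater2) {
  x <- cbind(as.numeric(rater1), as.numeric(rater2))
  if (nrow(x) < 3) stop_stage("icc", "need at least 3 rated items")
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r <= .Machine$double.eps) {
    warning("zero between-item variance: ICC undefined")
    return(list(single = NaN, average = NaN))
  }
  list(single = (ms_r - ms_e) / (ms_r + (k - 1) * ms_e),
       average = (ms_r - ms_e) / ms_r)
}

#' Spearman correlations among divergent-thinking indices
#'
#' Natural-log transforms the skewed count-like indices (by default
#' `flexibility`, `fluency`, `creativity_sum`) before correlating; since some
#' synthetic scores can be zero, `log1p` is substituted (and reported) when a
#' zero or negative value is present. Spearman rank correlations with
#' two-sided p-values are returned for all pairs.
#'
#' @param scores Data frame containing at least the columns in `vars`.
#' @param vars Columns to correlate.
#' @param log_vars Subset of `vars` to log-transform (Spearman correlations
#'   are invariant to this monotone transform; it is applied for parity with
#'   reporting conventions).
#' @return List with matrices `rho` and `p`, and `log_substituted`, the
#'   variables where `log1p` replaced `log`.
#' @export
correlate_indices <- function(scores,
                              vars = c("flexibility", "fluency",
                                       "creativity_sum", "odt"),
                              log_vars = c("flexibility", "fluency",
                                           "creativity_sum")) {
  stopifnot(all(vars %in% names(scores)))
  if (nrow(scores) < 5) stop_stage("correlate", "need at least 5 participants")
  dat <- scores[, vars, drop = FALSE]
  substituted <- character(0)
  for (v in intersect(log_vars, vars)) {
    x <- as.numeric(dat[[v]])
    if (any(x <= 0)) {
      dat[[v]] <- log1p(x)
      substituted <- c(substituted, v)
    } else {
      dat[[v]] <- log(x)
    }
  }
  p <- length(vars)
  rho <- diag(1, p); pval <- matrix(NA_real_, p, p)
  dimnames(rho) <- dimnames(pval) <- list(vars, vars)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ct <- suppressWarnings(
        stats::cor.test(dat[[i]], dat[[j]], method = "spearman",
                        exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pval[i, j] <- pval[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = pval, log_substituted = substituted)
}

#' Median-split group assignment
#'
#' Sorts participants by score (stable sort with participant id as
#' tie-breaker) and assigns the lower half to `"low"` and the upper half to
#' `"high"`, so both groups have exactly n/2 members for even n. Ties that
#' span the boundary are broken by id order and reported with a warning, as
#' is the extra `"low"` member for odd n.
#'
#' @param scores Named numeric vector (names = participant ids) or a data
#'   frame with columns `participant` and the column named in `variable`.
#' @param variable Name of the score column when `scores` is a data frame.
#' @return Data frame with columns `participant` and `group`
#'   (factor low/high); attributes `variable` and `threshold` (the median).
#' @export
median_split <- function(scores, variable = "score") {
  if (is.data.frame(scores)) {
    if (!variable %in% names(scores)) {
      stop_stage("median_split", "grouping variable '", variable,
                 "' not found in scores table")
    }
    values <- stats::setNames(as.numeric(scores[[variable]]),
                              as.character(scores$participant))
  } else {
    values <- scores
  }
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop_stage("median_split", "scores must carry unique participant ids")
  }
  n <- length(values)
  ord <- order(values, names(values), method = "radix")
  n_low <- ceiling(n / 2)
  if (n %% 2 == 1) warning("odd n: middle participant assigned to 'low'")
  grp <- rep("high", n)
  grp[seq_len(n_low)] <- "low"
  boundary <- values[ord][n_low]
  if (n_low < n && values[ord][n_low + 1] == boundary) {
    warning("tie at the median boundary broken by participant id order")
  }
  out <- data.frame(participant = names(values)[ord], group = grp,
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant), , drop = FALSE]
  rownames(out) <- NULL
  out$group <- factor(out$group, levels = c("low", "high"))
  attr(out, "variable") <- variable
  attr(out, "threshold") <- stats::median(values)
  out
}

#' Two-sample Student t-test with Cohen's d
#'
#' Pooled-variance (Student) two-sample t-test, two-sided, with Cohen's d
#' computed from the pooled standard deviation. The statistic is
#' `t = (mean(x) - mean(y)) / SE_pooled`, so its sign follows the first
#' argument.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `t`, `df`, `p`, `d`, `mean_x`, `mean_y`, and
#'   `degenerate` (TRUE when the pooled variance is zero, in which case `t`
#'   is signed infinity, or NaN for identical constants).
#' @export
compare_groups <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_stage("compare_groups", "need >= 2 per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  diff <- mean(x) - mean(y)
  df <- n1 + n2 - 2
  if (sp2 <= 0) {
    warning("zero pooled variance: t is degenerate")
    tval <- ifelse(diff == 0, NaN, sign(diff) * Inf)
    return(list(t = tval, df = df, p = ifelse(diff == 0, NaN, 0),
                d = ifelse(diff == 0, NaN, sign(diff) * Inf),
                mean_x = mean(x), mean_y = mean(y), degenerate = TRUE))
  }
  tval <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       d = diff / sqrt(sp2), mean_x = mean(x), mean_y = mean(y),
       degenerate = FALSE)
}
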