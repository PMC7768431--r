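# Reading, cleaning, binarizing and cross-group equating of semantic verbal
# fluency responses.

#' Load long-format fluency responses
#'
#' Reads a delimited text file with one row per produced response. The file
#' must have a header with columns `participant`, `response` and `order`
#' (1-based position of the response in the participant's list). Tokens are
#' lower-cased and whitespace-trimmed; blank responses are dropped; the input
#' row order is preserved.
#'
#' @param path Path to a CSV (default) or TSV file; the delimiter is chosen
#'   from the file extension (`.tsv`/`.txt` use tab).
#' @param sep Optional explicit field separator overriding the extension rule.
#' @return A data frame with columns `participant` (character), `response`
#'   (character, normalized) and `order` (integer).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("participant,response,order", "P1,Dog,1", "P1, cat ,2"), f)
#' load_responses(f)
#' @export
load_responses <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop_stage("load_responses", "file not found: ", path)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           fileEncoding = "UTF-8", comment.char = "",
                           stringsAsFactors = FALSE)
  required <- c("participant", "response", "order")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop_stage("load_responses", "missing required column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  tab$response <- normalize_token(tab$response)
  tab <- tab[!is.na(tab$response) & nzchar(tab$response), , drop = FALSE]
  tab$order <- as.integer(tab$order)
  if (anyNA(tab$order) || any(tab$order < 1)) {
    stop_stage("load_responses", "column 'order' must contain integers >= 1")
  }
  key <- paste(tab$participant, tab$order, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), , drop = FALSE][1, ]
    stop_stage("load_responses", "duplicate (participant, order) pair: ",
               dup$participant, ", ", dup$order)
  }
  rownames(tab) <- NULL
  tab[, required]
}

# Lower-case, trim, and apply Unicode NFC normalization so that visually
# identical tokens compare equal regardless of composed/decomposed encoding.
normalize_token <- function(x) {
  x <- stringi::stri_trans_nfc(enc2utf8(as.character(x)))
  tolower(trimws(x))
}

#' Validate and normalize a lemma map
#'
#' A lemma map sends surface forms (plurals, spelling variants) to canonical
#' forms. The map must be idempotent: every canonical form either maps to
#' itself or does not appear as a surface form.
#'
#' @param map Named character vector (`names` = surface form, value =
#'   canonical form), or a two-column data frame `(surface, canonical)`.
#' @return A named character vector with normalized tokens.
#' @export
as_lemma_map <- function(map) {
  if (is.null(map)) return(character(0))
  if (is.data.frame(map)) {
    if (ncol(map) < 2) stop_stage("lemma_map", "lemma map needs two columns")
    map <- stats::setNames(as.character(map[[2]]), as.character(map[[1]]))
  }
  surfaces <- normalize_token(names(map))
  canon <- normalize_token(unname(map))
  names(canon) <- surfaces
  # idempotence: canonical forms, if present as surfaces, must be fixed points
  hit <- canon[match(canon, surfaces)]
  bad <- !is.na(hit) & hit != canon
  if (any(bad)) {
    stop_stage("lemma_map", "map is not idempotent for: ",
               paste(unique(canon[bad]), collapse = ", "))
  }
  canon
}

#' Clean fluency responses and build a binary incidence matrix
#'
#' Applies, in order: lemma normalization (table-driven with a fallback
#' heuristic stripping a final "s" when the singular is in the lexicon),
#' lexicon filtering (non-category members dropped when a lexicon is given),
#' within-participant repetition removal (only the first occurrence of each
#' canonical token kept), and removal of idiosyncratic tokens produced by
#' fewer than `min_producers` participants in the whole sample. The result is
#' a participants x words binary matrix: cell (j, i) is 1 when participant j
#' produced word i.
#'
#' @param records Data frame as returned by [load_responses()].
#' @param lemma_map Optional lemma map (see [as_lemma_map()]).
#' @param category_lexicon Optional character vector of admissible canonical
#'   tokens; responses outside it are dropped.
#' @param min_producers Minimum number of distinct producers a token needs to
#'   be retained (default 2, the idiosyncratic-response rule).
#' @return An integer 0/1 matrix with participant ids as row names and
#'   canonical tokens as column names, ordered alphabetically. An `attrition`
#'   attribute records how many response records each rule removed.
#' @export
preprocess_responses <- function(records, lemma_map = NULL,
                                 category_lexicon = NULL, min_producers = 2) {
  stopifnot(all(c("participant", "response", "order") %in% names(records)))
  lemma_map <- as_lemma_map(lemma_map)
  lexicon <- if (is.null(category_lexicon)) NULL else
    unique(normalize_token(category_lexicon))

  tok <- normalize_token(records$response)
  n_raw <- length(tok)

  # lemma normalization: explicit map first, then the plural heuristic
  mapped <- lemma_map[tok]
  tok <- ifelse(is.na(mapped), tok, mapped)
  if (!is.null(lexicon)) {
    stripped <- sub("s$", "", tok)
    use <- !(tok %in% lexicon) & stripped %in% lexicon
    tok[use] <- stripped[use]
  }

  keep_lex <- if (is.null(lexicon)) rep(TRUE, length(tok)) else tok %in% lexicon
  n_nonlex <- sum(!keep_lex)

  df <- data.frame(participant = as.character(records$participant),
                   token = tok, order = as.integer(records$order),
                   stringsAsFactors = FALSE)[keep_lex, , drop = FALSE]
  df <- df[order(df$participant, df$order), , drop = FALSE]
  first <- !duplicated(paste(df$participant, df$token, sep = "\r"))
  n_repeat <- sum(!first)
  df <- df[first, , drop = FALSE]

  producers <- tapply(df$participant, df$token,
                      function(p) length(unique(p)))
  common <- names(producers)[producers >= min_producers]
  n_idio <- sum(!(df$token %in% common))
  df <- df[df$token %in% common, , drop = FALSE]

  attrition <- c(raw = n_raw, non_lexicon = n_nonlex,
                 repetition = n_repeat, idiosyncratic = n_idio,
                 kept = nrow(df))
  if (nrow(df) == 0) {
    stop_stage("preprocess",
               "all responses eliminated (raw=", n_raw,
               ", non-lexicon=", n_nonlex, ", repetitions=", n_repeat,
               ", idiosyncratic=", n_idio, ")")
  }

  participants <- sort(unique(as.character(records$participant)))
  words <- sort(unique(df$token))
  mat <- matrix(0L, nrow = length(participants), ncol = length(words),
                dimnames = list(participants, words))
  mat[cbind(match(df$participant, participants), match(df$token, words))] <- 1L
  attr(mat, "attrition") <- attrition
  mat
}

#' Restrict two group incidence matrices to a shared equated word set
#'
#' Keeps exactly the tokens produced by at least `min_per_group` participants
#' in *both* groups, so the two group networks are built over identical node
#' sets. Column order is identical in both outputs; participant rows are
#' untouched.
#'
#' @param mat_low,mat_high Binary incidence matrices over the same canonical
#'   token universe (columns missing from one matrix count as all-zero).
#' @param min_per_group Minimum per-group producer count (default 2).
#' @return A list with elements `low` and `high` (the restricted matrices)
#'   and `words` (the equated token set).
#' @export
equate_groups <- function(mat_low, mat_high, min_per_group = 2) {
  universe <- sort(union(colnames(mat_low), colnames(mat_high)))
  expand <- function(m) {
    out <- matrix(0L, nrow = nrow(m), ncol = length(universe),
                  dimnames = list(rownames(m), universe))
    out[, colnames(m)] <- m
    out
  }
  lo <- expand(mat_low)
  hi <- expand(mat_high)
  keep <- colSums(lo) >= min_per_group & colSums(hi) >= min_per_group
  words <- universe[keep]
  if (length(words) < 4) {
    stop_stage("equate_groups",
               "equated word set has ", length(words),
               " tokens; at least 4 are required for TMFG filtering")
  }
  list(low = lo[, words, drop = FALSE],
       high = hi[, words, drop = FALSE],
       words = words)
}

#' Write an incidence matrix to CSV
#'
#' @param mat Binary incidence matrix.
#' @param path Output file; participant ids go in the first column.
#' @export
write_incidence <- function(mat, path) {
  df <- data.frame(participant = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
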