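test_that("load_responses normalizes case and whitespace, preserves order", {
  f <- write_response_csv(c("P1,Dog,1", "P1, cat ,2", "P1,dog,3"))
  rec <- load_responses(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$response, c("dog", "cat", "dog"))
  expect_equal(rec$order, 1:3)
})

test_that("load_responses handles empty and malformed files", {
  empty <- write_response_csv(character(0))
  expect_equal(nrow(load_responses(empty)), 0)

  f <- tempfile(fileext = ".csv")
  writeLines(c("participant,word,order", "P1,dog,1"), f)
  expect_error(load_responses(f), "missing required column.*response")

  dup <- write_response_csv(c("P1,dog,1", "P1,cat,1"))
  expect_error(load_responses(dup), "duplicate")
})

test_that("preprocessing applies lemma map, lexicon and repetition rules", {
  rec <- make_records("P1", c("dogs", "dog", "unicorn"), 1:3)
  m <- preprocess_responses(rec, lemma_map = c(dogs = "dog"),
                            category_lexicon = c("dog", "cat"),
                            min_producers = 1)
  expect_equal(dim(m), c(1, 1))
  expect_equal(colnames(m), "dog")
  expect_equal(unname(m[1, 1]), 1L)
})

test_that("idiosyncratic tokens require min_producers distinct producers", {
  rec <- make_records(c("P1", "P2", "P2"), c("cat", "cat", "axolotl"),
                      c(1, 1, 2))
  m <- preprocess_responses(rec, min_producers = 2)
  expect_equal(colnames(m), "cat")
  expect_equal(unname(colSums(m)), 2)
  expect_error(
    preprocess_responses(make_records("P1", "axolotl", 1), min_producers = 2),
    "all responses eliminated")
})

test_that("incidence matrix agrees with a brute-force producer tally", {
  set.seed(7)
  lexicon <- sprintf("animal%02d", 1:40)
  rec <- do.call(rbind, lapply(1:58, function(p) {
    k <- sample(5:14, 1)
    make_records(sprintf("P%02d", p), sample(lexicon, k), seq_len(k))
  }))
  m <- preprocess_responses(rec, min_producers = 2)

  # oracle: tally distinct producers per token from the raw records
  tally <- table(unique(rec[c("participant", "response")])$response)
  expect_setequal(colnames(m), names(tally)[tally >= 2])
  for (w in colnames(m)) {
    producers <- unique(rec$participant[rec$response == w])
    expect_equal(sum(m[, w]), length(producers))
    expect_setequal(rownames(m)[m[, w] == 1], producers)
  }
})

test_that("preprocessing is insensitive to input row order", {
  set.seed(11)
  rec <- do.call(rbind, lapply(1:10, function(p) {
    k <- sample(4:8, 1)
    make_records(sprintf("P%02d", p),
                 sample(sprintf("w%02d", 1:20), k), seq_len(k))
  }))
  m1 <- preprocess_responses(rec, min_producers = 2)
  m2 <- preprocess_responses(rec[sample(nrow(rec)), ], min_producers = 2)
  expect_identical(m1, m2)
})

test_that("group equating keeps exactly the >=2-in-both tokens", {
  lo <- random_incidence(29, 40, 0.25, seed = 21)
  hi <- random_incidence(29, 40, 0.25, seed = 22)
  eq <- equate_groups(lo, hi)

  oracle <- intersect(colnames(lo)[colSums(lo) >= 2],
                      colnames(hi)[colSums(hi) >= 2])
  expect_setequal(eq$words, oracle)
  expect_identical(colnames(eq$low), colnames(eq$high))
  expect_true(all(colSums(eq$low) >= 2))
  expect_true(all(colSums(eq$high) >= 2))

  # symmetry: swapping arguments swaps outputs, same word set
  eq2 <- equate_groups(hi, lo)
  expect_identical(eq2$words, eq$words)
  expect_identical(eq2$low, eq$high)

  # a word popular in one group only is dropped from both
  lo2 <- lo; lo2[, "w01"] <- c(rep(1L, 5), rep(0L, 24))
  hi2 <- hi; hi2[, "w01"] <- c(1L, rep(0L, 28))
  expect_false("w01" %in% equate_groups(lo2, hi2)$words)
})

test_that("equating fails below the 4-node TMFG minimum", {
  lo <- matrix(1L, 3, 3, dimnames = list(paste0("L", 1:3), c("a", "b", "c")))
  hi <- matrix(0L, 3, 3, dimnames = list(paste0("H", 1:3), c("a", "b", "c")))
  expect_error(equate_groups(lo, hi), "at least 4")
})
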