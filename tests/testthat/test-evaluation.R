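test_that("exact counts and prf follow the CoNLL conventions", {
  A <- entity_spans(c(0L, 10L), c(5L, 20L), "ADR")
  expect_equal(exact_counts(A, A), list(TP = 2L, FP = 0L, FN = 0L))
  expect_equal(exact_counts(A[1, ], entity_spans()),
               list(TP = 0L, FP = 0L, FN = 1L))
  off <- entity_spans(c(0L, 10L), c(5L, 19L), "ADR")  # one boundary off by 1
  expect_equal(exact_counts(A, off), list(TP = 1L, FP = 1L, FN = 1L))

  expect_equal(unname(prf(list(TP = 2, FP = 0, FN = 0))), c(1, 1, 1))
  expect_equal(unname(prf(list(TP = 1, FP = 1, FN = 1))), c(0.5, 0.5, 0.5))
  expect_equal(unname(prf(list(TP = 0, FP = 0, FN = 0))), c(0, 0, 0))
})

test_that("partial matching credits token overlap per term", {
  # gold "upset stomach" (2 tokens), prediction "stomach" alone
  gold <- data.frame(first = 1L, last = 2L)
  pred <- data.frame(first = 2L, last = 2L)
  pr <- partial_sentence(gold, pred)
  expect_equal(unname(pr), c(1.0, 0.5))

  expect_equal(unname(partial_sentence(gold, gold)), c(1, 1))

  # one 4-token gold term vs two disjoint 1-token predictions
  gold4 <- data.frame(first = 1L, last = 4L)
  pred2 <- data.frame(first = c(1L, 3L), last = c(1L, 3L))
  pr <- partial_sentence(gold4, pred2)
  expect_equal(unname(pr), c(1.0, 0.5))

  # overlap credit is capped at 1 even with multiple gold intersections
  gold2 <- data.frame(first = c(1L, 3L), last = c(2L, 4L))
  wide <- data.frame(first = 1L, last = 4L)
  pr <- partial_sentence(gold2, wide)
  expect_lte(pr[["precision"]], 1)
})

test_that("corpus evaluation handles identity, misses, and empty sentences", {
  g1 <- data.frame(first = c(1L, 4L), last = c(2L, 4L))
  g2 <- data.frame(first = 2L, last = 3L)
  none <- data.frame(first = integer(), last = integer())
  gold <- list(g1, g2, none)

  for (m in c("exact", "partial")) {
    r <- evaluate_corpus(gold, gold, mode = m)
    expect_equal(r$precision, 1)
    expect_equal(r$recall, 1)
    expect_equal(r$f1, 1)
  }
  # empty predictions against gold-bearing sentences: recall is 0 in both
  # modes (the all-empty third sentence is excluded here; under the default
  # convention it counts as perfectly handled and would enter the average)
  empty_pred <- list(none, none)
  for (m in c("exact", "partial"))
    expect_equal(evaluate_corpus(gold[1:2], empty_pred, mode = m)$recall, 0)
  expect_equal(evaluate_corpus(gold, list(none, none, none), mode = "partial",
                               empty_sentence = "skip")$recall, 0)
  expect_equal(evaluate_corpus(gold, list(none, none, none),
                               mode = "partial")$recall, 1 / 3)

  expect_error(evaluate_corpus(gold, gold[1:2]), "same sentences")
})

test_that("exact mode agrees with an independent set-comparison oracle", {
  set.seed(21)
  for (rep in 1:50) {
    ns <- sample(3:8, 1)
    gold <- list(); pred <- list()
    for (i in seq_len(ns)) {
      mk <- function() {
        m <- sample(0:3, 1)
        f <- sort(sample(1:10, m))
        data.frame(first = f, last = pmin(10L, f + sample(0:2, m, TRUE)))
      }
      gold[[i]] <- mk(); pred[[i]] <- mk()
    }
    r <- evaluate_corpus(gold, pred, mode = "exact")
    # naive oracle: string keys, set arithmetic over the pooled corpus
    keys <- function(tt, i) if (nrow(tt) == 0) character() else
      paste(i, tt$first, tt$last)
    gk <- unlist(lapply(seq_len(ns), function(i) unique(keys(gold[[i]], i))))
    pk <- unlist(lapply(seq_len(ns), function(i) unique(keys(pred[[i]], i))))
    tp <- length(intersect(gk, pk))
    p <- if (length(pk) > 0) tp / length(pk) else 0
    rr <- if (length(gk) > 0) tp / length(gk) else 0
    expect_equal(r$precision, p)
    expect_equal(r$recall, rr)
  }
})

test_that("evaluation is invariant to sentence order", {
  set.seed(22)
  gold <- lapply(1:6, function(i) {
    f <- sort(sample(1:8, sample(0:2, 1)))
    data.frame(first = f, last = f + 1L)
  })
  pred <- lapply(1:6, function(i) {
    f <- sort(sample(1:8, sample(0:2, 1)))
    data.frame(first = f, last = f + 1L)
  })
  perm <- sample(6)
  for (m in c("exact", "partial")) {
    a <- evaluate_corpus(gold, pred, mode = m)
    b <- evaluate_corpus(gold[perm], pred[perm], mode = m)
    expect_equal(a$precision, b$precision)
    expect_equal(a$recall, b$recall)
  }
})

test_that("partial matching relaxes exact matching under one-to-one overlap", {
  set.seed(23)
  for (rep in 1:100) {
    # construct sentences where every predicted term intersects at most one
    # gold term and vice versa: perturb each gold term's boundaries locally
    ns <- sample(2:5, 1)
    gold <- list(); pred <- list()
    for (i in seq_len(ns)) {
      anchors <- seq(1, by = 6, length.out = sample(1:3, 1))
      g <- data.frame(first = anchors, last = anchors + sample(0:2, length(anchors), TRUE))
      keep <- stats::runif(length(anchors)) < 0.8
      p <- g[keep, , drop = FALSE]
      jitter <- sample(-1:1, nrow(p), TRUE)
      p$first <- pmax(p$first + jitter, p$first - 1L)
      p$last <- pmax(p$first, p$last + sample(-1:1, nrow(p), TRUE))
      gold[[i]] <- g; pred[[i]] <- p
    }
    ex <- evaluate_corpus(gold, pred, mode = "exact", macro_exact = TRUE)
    pa <- evaluate_corpus(gold, pred, mode = "partial",
                          empty_sentence = "skip")
    expect_gte(pa$precision + 1e-12, ex$precision)
    expect_gte(pa$recall + 1e-12, ex$recall)
  }
})

test_that("F1 is bounded by the geometric and arithmetic P/R means", {
  set.seed(24)
  for (rep in 1:50) {
    tp <- sample(0:10, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    v <- prf(list(TP = tp, FP = fp, FN = fn))
    expect_lte(v[["f1"]], sqrt(v[["precision"]] * v[["recall"]]) + 1e-12)
    expect_lte(v[["f1"]], (v[["precision"]] + v[["recall"]]) / 2 + 1e-12)
  }
})
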