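test_that("sequence score matches naive summation", {
  zero <- score_lattice(matrix(0, 3, 2))
  expect_equal(crf_sequence_score(zero, c(1, 2, 1)), 0)

  one <- score_lattice(matrix(c(1.5, -0.5), 1, 2))
  expect_equal(crf_sequence_score(one, 1), 1.5)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:6, 1); k <- 3
    lat <- rand_lattice(n, k)
    path <- sample(k, n, replace = TRUE)
    expect_equal(crf_sequence_score(lat, path), naive_path_score(lat, path))
  }
  expect_error(crf_sequence_score(zero, c(1, 2)), "length")
})

test_that("log partition equals exhaustive enumeration", {
  zero <- score_lattice(matrix(0, 3, 2))
  expect_equal(crf_log_partition(zero), 3 * log(2))

  ab <- score_lattice(matrix(c(0.7, -1.3), 1, 2))
  expect_equal(crf_log_partition(ab), log(exp(0.7) + exp(-1.3)))

  set.seed(12)
  for (i in 1:200) {
    n <- sample(1:6, 1); k <- sample(2:4, 1)
    lat <- rand_lattice(n, k)
    expect_equal(crf_log_partition(lat), enum_log_partition(lat),
                 tolerance = 1e-8)
  }
})

test_that("path probabilities normalize and NLL is non-negative", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(1:5, 1); k <- sample(2:3, 1)
    lat <- rand_lattice(n, k)
    logZ <- crf_log_partition(lat)
    probs <- exp(enum_scores(lat) - logZ)
    expect_equal(sum(probs), 1, tolerance = 1e-10)
    gold <- sample(k, n, replace = TRUE)
    expect_gte(crf_nll(lat, gold), 0)
  }

  zero <- score_lattice(matrix(0, 2, 2))
  expect_equal(crf_nll(zero, c(1, 2)), 2 * log(2))

  # unary mass piled on the gold path drives the NLL toward zero
  u <- matrix(0, 4, 3); gold <- c(1, 2, 3, 2)
  u[cbind(1:4, gold)] <- 10
  expect_lt(crf_nll(score_lattice(u), gold), 0.01)
})

test_that("analytic NLL gradients match central finite differences", {
  set.seed(14)
  worst <- 0
  for (i in 1:50) {
    n <- sample(2:5, 1); k <- 3
    lat <- rand_lattice(n, k, scale = 1)
    gold <- sample(k, n, replace = TRUE)
    g <- crf_nll_grad(lat, gold)
    expect_equal(g$nll, crf_nll(lat, gold), tolerance = 1e-10)
    eps <- 1e-6
    for (slot in c("unary", "transitions", "start", "stop")) {
      p <- lat[[slot]]
      idx <- sample(length(p), min(4, length(p)))
      for (j in idx) {
        lp <- lat; lp[[slot]][j] <- p[j] + eps
        lm <- lat; lm[[slot]][j] <- p[j] - eps
        fd <- (crf_nll(do.call(score_lattice, lp), gold) -
                 crf_nll(do.call(score_lattice, lm), gold)) / (2 * eps)
        an <- g[[slot]][j]
        rel <- abs(fd - an) / max(1, abs(fd), abs(an))
        worst <- max(worst, rel)
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("viterbi attains the enumeration maximum with lowest-index ties", {
  one <- score_lattice(matrix(c(2, 1, 0), 1, 3))
  v <- crf_viterbi(one)
  expect_equal(v$path, 1L)
  expect_equal(v$score, 2)

  zero <- score_lattice(matrix(0, 4, 3))
  v <- crf_viterbi(zero)
  expect_equal(v$path, rep(1L, 4))
  expect_equal(v$score, 0)

  set.seed(15)
  for (i in 1:200) {
    n <- sample(1:6, 1); k <- sample(2:4, 1)
    lat <- rand_lattice(n, k)
    v <- crf_viterbi(lat)
    expect_equal(v$score, max(enum_scores(lat)), tolerance = 1e-10)
    expect_equal(crf_sequence_score(lat, v$path), v$score, tolerance = 1e-10)
  }
})

test_that("viterbi dominates sampled paths and is shift/scale covariant", {
  set.seed(16)
  for (i in 1:10) {
    n <- sample(2:6, 1); k <- 3
    lat <- rand_lattice(n, k)
    v <- crf_viterbi(lat)
    for (j in 1:100) {
      p <- sample(k, n, replace = TRUE)
      expect_gte(v$score + 1e-12, crf_sequence_score(lat, p))
    }
    # adding c to every unary at one position shifts logZ by exactly c
    cshift <- stats::rnorm(1)
    lat2 <- lat; lat2$unary[1, ] <- lat2$unary[1, ] + cshift
    expect_equal(crf_log_partition(do.call(score_lattice, lat2)),
                 crf_log_partition(lat) + cshift, tolerance = 1e-10)
    # doubling unary scores cannot change the argmax when it is unique
    lat3 <- lat; lat3$unary <- lat3$unary * 2
    lat3$transitions <- lat3$transitions * 2
    lat3$start <- lat3$start * 2; lat3$stop <- lat3$stop * 2
    expect_equal(crf_viterbi(do.call(score_lattice, lat3))$path, v$path)
  }
})

test_that("constrained viterbi enforces the BIO grammar", {
  tagset <- c("O", "B-ADR", "I-ADR")
  forb <- bio_forbidden(tagset)
  expect_true(all(forb$start == 3L))
  expect_true(nrow(forb$pairs) == 1 && all(forb$pairs == c(1L, 3L)))

  set.seed(17)
  # empty constraint set: identical to plain viterbi
  for (i in 1:20) {
    lat <- rand_lattice(sample(1:5, 1), 3)
    a <- crf_viterbi(lat)
    b <- crf_constrained_viterbi(lat, list(pairs = NULL, start = integer()))
    expect_equal(a$path, b$path)
    expect_equal(a$score, b$score)
  }

  # adversarial lattice whose unconstrained argmax is O -> I-ADR
  u <- matrix(c(5, -5,      # position 1: O strongly preferred
                -5, 5), 2, 2, byrow = TRUE)
  u <- cbind(u[, 1], -10, u[, 2])   # tags: O, B-ADR, I-ADR
  lat <- score_lattice(u)
  expect_equal(crf_viterbi(lat)$path, c(1L, 3L))
  v <- crf_constrained_viterbi(lat, forb)
  expect_false(identical(v$path, c(1L, 3L)))
  tags <- tagset[v$path]
  expect_true(tags[1] != "I-ADR")

  # random lattices: equals brute force over BIO-valid paths only
  is_valid <- function(p) {
    if (p[1] == 3L) return(FALSE)
    if (length(p) > 1)
      for (t in 2:length(p)) if (p[t] == 3L && p[t - 1] == 1L) return(FALSE)
    TRUE
  }
  for (i in 1:100) {
    n <- sample(1:5, 1)
    lat <- rand_lattice(n, 3)
    v <- crf_constrained_viterbi(lat, forb)
    paths <- enum_paths(n, 3)
    valid <- apply(paths, 1L, is_valid)
    best <- max(apply(paths[valid, , drop = FALSE], 1L,
                      function(p) naive_path_score(lat, p)))
    expect_equal(v$score, best, tolerance = 1e-10)
    expect_true(is_valid(v$path))
  }
})

test_that("batched NLL over padded sequences equals per-sequence sums", {
  set.seed(18)
  for (i in 1:20) {
    B <- sample(2:4, 1); k <- 3
    lens <- sample(1:6, B, replace = TRUE)
    Tm <- max(lens)
    tr <- matrix(stats::rnorm(k * k), k, k)
    st <- stats::rnorm(k); en <- stats::rnorm(k)
    unary <- array(stats::rnorm(B * Tm * k), c(B, Tm, k))
    gold <- matrix(sample(k, B * Tm, replace = TRUE), B, Tm)
    res <- crf_batch_nll_grad(unary, lens, tr, st, en, gold)
    ref <- 0
    for (b in seq_len(B)) {
      lat <- score_lattice(matrix(unary[b, seq_len(lens[b]), ], lens[b], k),
                           tr, st, en)
      ref <- ref + crf_nll(lat, gold[b, seq_len(lens[b])])
    }
    expect_equal(res$nll, ref, tolerance = 1e-8)
    # padded positions carry zero gradient
    for (b in seq_len(B)) if (lens[b] < Tm)
      expect_true(all(res$unary[b, (lens[b] + 1):Tm, ] == 0))
  }
})
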