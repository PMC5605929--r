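test_that("brat reader handles empty, annotated, and malformed input", {
  d <- read_brat("", "", doc_id = "empty")
  expect_s3_class(d, "adr_document")
  expect_equal(nrow(d$spans), 0)

  ex <- intro_example()
  d <- read_brat(ex$text, ex$ann, doc_id = "intro")
  expect_equal(nrow(d$spans), 4)
  expect_setequal(d$spans$text, ex$phrases)
  expect_equal(d$spans$text,
               substring(ex$text, d$spans$start + 1, d$spans$end))

  expect_error(read_brat("abc", "T1\tADR xx 2\tab"), "line 1")
  expect_error(read_brat("abc", "T1"), "malformed")
})

test_that("brat reader warns once when quoted text disagrees with offsets", {
  ex <- intro_example()
  # perturb the first record's start offset by one character
  lines <- strsplit(ex$ann, "\n")[[1]]
  parts <- strsplit(lines[1], "\t")[[1]]
  hp <- strsplit(parts[2], " ")[[1]]
  hp[2] <- as.integer(hp[2]) + 1L
  lines[1] <- paste(parts[1], paste(hp, collapse = " "), parts[3], sep = "\t")
  warns <- testthat::capture_warnings(
    d <- read_brat(ex$text, paste(lines, collapse = "\n")))
  expect_length(warns, 1)
  expect_equal(nrow(d$spans), 4)   # offsets kept as authoritative
})

test_that("discontinuous brat spans collapse to covering intervals", {
  text <- "pain in my left arm all day"
  ann <- "T1\tADR 0 4;16 19\tpain arm"
  d <- read_brat(text, ann)
  expect_equal(d$spans$start, 0L)
  expect_equal(d$spans$end, 19L)
  expect_true(d$spans$discontinuous)
})

test_that("brat pair files roundtrip through disk", {
  ex <- intro_example()
  d <- read_brat(ex$text, ex$ann, doc_id = "intro")
  tx <- tempfile(fileext = ".txt"); an <- tempfile(fileext = ".ann")
  write_brat_pair(d, tx, an)
  d2 <- read_brat_pair(tx, an)
  expect_equal(d2$text, d$text)
  expect_equal(d2$spans$start, d$spans$start)
  expect_equal(d2$spans$end, d$spans$end)
})

test_that("resolve_overlaps unions transitive overlap groups", {
  expect_equal(nrow(resolve_overlaps(entity_spans())), 0)

  disjoint <- entity_spans(c(10L, 30L), c(20L, 40L), "ADR")
  r <- resolve_overlaps(disjoint)
  expect_equal(r$start, c(10L, 30L))
  expect_equal(r$end, c(20L, 40L))

  chain <- entity_spans(c(10L, 15L, 28L), c(25L, 30L, 35L), "ADR")
  r <- resolve_overlaps(chain)
  expect_equal(r$start, 10L)
  expect_equal(r$end, 35L)
})

test_that("resolve_overlaps matches brute force and is idempotent", {
  set.seed(42)
  for (i in 1:200) {
    m <- sample(0:8, 1)
    start <- sample(0:60, m, replace = TRUE)
    len <- sample(1:12, m, replace = TRUE)
    sp <- entity_spans(start, start + len, "ADR")
    r <- resolve_overlaps(sp)
    oracle <- brute_resolve(sp$start, sp$end)
    expect_equal(r$start, oracle$start)
    expect_equal(r$end, oracle$end)
    # non-overlapping output
    if (nrow(r) > 1)
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    # idempotent
    r2 <- resolve_overlaps(r)
    expect_equal(r2$start, r$start)
    expect_equal(r2$end, r$end)
  }
})

test_that("spans_to_bio tags covered tokens and demands resolved input", {
  s <- mk_sentence(c("upset", "stomach"))
  sp <- entity_spans(0L, 13L, "ADR")
  expect_equal(spans_to_bio(s, sp), c("B-ADR", "I-ADR"))

  ex <- intro_example()
  doc <- read_brat(ex$text, ex$ann)
  sent <- doc_sentences(doc)[[1]]
  tags <- spans_to_bio(sent, resolve_overlaps(doc$spans, doc$text))
  expect_equal(sum(tags == "B-ADR"), 4)

  overlapping <- entity_spans(c(0L, 3L), c(8L, 13L), "ADR")
  expect_error(spans_to_bio(s, overlapping), "resolve_overlaps")
})

test_that("bio_to_spans decodes runs and repairs orphan I- tags", {
  s3 <- mk_sentence(c("a", "b", "c"))
  expect_equal(nrow(bio_to_spans(s3, c("O", "O", "O"))), 0)

  s4 <- mk_sentence(c("a", "b", "c", "d"))
  sp <- bio_to_spans(s4, c("B-ADR", "I-ADR", "O", "B-ADR"))
  expect_equal(nrow(sp), 2)

  sp <- bio_to_spans(s3, c("O", "I-ADR", "I-ADR"))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$start, s3$tokens$start[2])
  expect_error(bio_to_spans(s3, c("O", "I-ADR", "I-ADR"), mode = "strict"),
               "orphan")
  expect_error(bio_to_spans(s3, c("O", "O")), "length")
})

test_that("bio_to_spans agrees with an independent decoder on all length-3 sequences", {
  tags3 <- expand.grid(rep(list(c("O", "B-ADR", "I-ADR")), 3),
                       stringsAsFactors = FALSE)
  s <- mk_sentence(c("w1", "w2", "w3"))
  for (i in seq_len(nrow(tags3))) {
    tg <- unlist(tags3[i, ])
    got <- spans_to_terms(s, bio_to_spans(s, tg))
    want <- oracle_decode_bio(tg)
    expect_equal(got$first, want$first, info = paste(tg, collapse = " "))
    expect_equal(got$last, want$last, info = paste(tg, collapse = " "))
  }
})

test_that("span/BIO codec roundtrips on random token-aligned span sets", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(1:12, 1)
    s <- mk_sentence(sprintf("w%d", seq_len(n)))
    # sample non-overlapping token intervals
    first <- integer(); last <- integer()
    t0 <- 1L
    while (t0 <= n) {
      if (stats::runif(1) < 0.4) {
        len <- sample(1:min(3, n - t0 + 1L), 1)
        first <- c(first, t0); last <- c(last, t0 + len - 1L)
        t0 <- t0 + len + 1L
      } else t0 <- t0 + 1L
    }
    sp <- entity_spans(s$tokens$start[first], s$tokens$end[last], "ADR")
    back <- bio_to_spans(s, spans_to_bio(s, sp))
    expect_equal(back$start, sp$start)
    expect_equal(back$end, sp$end)
    # and the term view agrees with the sampled intervals
    tm <- spans_to_terms(s, back)
    expect_equal(tm$first, first)
    expect_equal(tm$last, last)
  }
})

test_that("tokenizer preserves the text it tokenizes", {
  texts <- c("I experienced shortness of breath, a sense of depression.",
             "1st pill (taken with food!) -- no issues...",
             "weight gain. dry mouth?  twitching",
             "")
  for (tx in texts) {
    toks <- tokenize_text(tx)
    if (nrow(toks) == 0) { expect_equal(gsub("\\s", "", tx), ""); next }
    expect_equal(toks$surface,
                 substring(tx, toks$start + 1, toks$end))
    # concatenating surfaces with recorded gaps reconstructs the text
    rebuilt <- substring(tx, 1, toks$start[1])
    for (i in seq_len(nrow(toks))) {
      gap_end <- if (i < nrow(toks)) toks$start[i + 1] else nchar(tx)
      rebuilt <- paste0(rebuilt, substring(tx, toks$start[i] + 1, gap_end))
    }
    expect_equal(rebuilt, tx)
  }
})

test_that("sentence splitting yields offset-true non-empty sentences", {
  text <- "I had nausea. Then dizziness! It faded?  All good now"
  doc <- adr_document("d", text)
  sents <- doc_sentences(doc)
  expect_equal(length(sents), 4)
  for (s in sents)
    expect_equal(s$tokens$surface,
                 substring(text, s$tokens$start + 1, s$tokens$end))
})

test_that("CoNLL writer/reader roundtrip is bit-exact", {
  sents <- list(mk_sentence(c("upset", "stomach", ".")),
                mk_sentence(c("no", "problems")))
  tags <- list(c("B-ADR", "I-ADR", "O"), c("O", "O"))
  f1 <- tempfile()
  write_conll(sents, tags, f1)
  rd <- read_conll(f1)
  expect_equal(length(rd$sentences), 2)
  expect_equal(rd$tags, tags)
  expect_equal(lapply(rd$sentences, function(s) s$tokens$surface),
               lapply(sents, function(s) s$tokens$surface))
  f2 <- tempfile()
  write_conll(rd$sentences, rd$tags, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("split_corpus partitions documents deterministically", {
  docs <- lapply(1:10, function(i) adr_document(paste0("d", i), "text here"))
  sp <- split_corpus(docs, 0.7, seed = 5)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  ids <- function(x) vapply(x, function(d) d$doc_id, character(1))
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(docs))
  sp2 <- split_corpus(docs, 0.7, seed = 5)
  expect_identical(ids(sp$train), ids(sp2$train))
  sp3 <- split_corpus(docs, 0.7, seed = 6)
  expect_false(identical(ids(sp$train), ids(sp3$train)))

  big <- lapply(1:1250, function(i) adr_document(paste0("r", i), "x y"))
  spb <- split_corpus(big, 0.7, seed = 1)
  expect_length(spb$train, 875)
  expect_length(spb$test, 375)

  expect_error(split_corpus(docs[1], 0.7, 1), "at least 2")
})
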