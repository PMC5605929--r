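# Shared fixtures and independent oracles. Everything here is deliberately
# naive (enumeration, brute force) so it cannot share bugs with the
# implementation under test.

# Build a sentence from bare words, offsets as if joined by single spaces.
mk_sentence <- function(words, doc_id = "t", index = 1L) {
  ends <- cumsum(nchar(words) + 1L) - 1L
  starts <- c(0L, utils::head(ends, -1L) + 1L)
  structure(list(doc_id = doc_id, index = index,
                 tokens = data.frame(surface = words, start = starts,
                                     end = ends, stringsAsFactors = FALSE)),
            class = "adr_sentence")
}

# The motivating review sentence with its four annotated reactions.
intro_example <- function() {
  text <- paste("1st pill taken with food, a few hours after I experienced",
                "shortness of breath, a sense of depression, cramping,",
                "upset stomach")
  phrases <- c("shortness of breath", "depression", "cramping",
               "upset stomach")
  ann <- vapply(seq_along(phrases), function(i) {
    s <- regexpr(phrases[i], text, fixed = TRUE)
    sprintf("T%d\tADR %d %d\t%s", i, s - 1L, s - 1L + nchar(phrases[i]),
            phrases[i])
  }, character(1))
  list(text = text, ann = paste(ann, collapse = "\n"), phrases = phrases)
}

rand_lattice <- function(n, k, scale = 2) {
  score_lattice(matrix(stats::rnorm(n * k, sd = scale), n, k),
                matrix(stats::rnorm(k * k, sd = scale), k, k),
                stats::rnorm(k, sd = scale), stats::rnorm(k, sd = scale))
}

# All |Y|^n tag paths as rows.
enum_paths <- function(n, k) as.matrix(expand.grid(rep(list(seq_len(k)), n)))

# Path score by naive term-by-term summation (loop-free of the packaged
# recursions).
naive_path_score <- function(lat, path) {
  s <- lat$start[path[1]] + lat$stop[path[length(path)]]
  for (t in seq_along(path)) s <- s + lat$unary[t, path[t]]
  if (length(path) > 1)
    for (t in 2:length(path)) s <- s + lat$transitions[path[t - 1], path[t]]
  s
}

enum_scores <- function(lat) {
  apply(enum_paths(nrow(lat$unary), ncol(lat$unary)), 1L,
        function(p) naive_path_score(lat, p))
}

# log-sum-exp of all path scores by enumeration.
enum_log_partition <- function(lat) {
  s <- enum_scores(lat)
  m <- max(s)
  m + log(sum(exp(s - m)))
}

# Brute-force transitive-overlap resolution: connected components of the
# strict-intersection graph, one covering interval per component.
brute_resolve <- function(start, end) {
  n <- length(start)
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && start[i] < end[j] && start[j] < end[i] &&
          comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cid)
    data.frame(start = min(start[comp == cid]), end = max(end[comp == cid]))))
  out[order(out$start), , drop = FALSE]
}

# Independent BIO decoder used as the codec oracle: returns first/last token
# indices, treating an orphan I- as an opener (repair semantics).
oracle_decode_bio <- function(tags) {
  first <- integer(); last <- integer()
  open <- FALSE
  for (i in seq_along(tags)) {
    if (tags[i] == "O") open <- FALSE
    else if (grepl("^B-", tags[i]) || !open) {
      first <- c(first, i); last <- c(last, i); open <- TRUE
    } else last[length(last)] <- i
  }
  data.frame(first = first, last = last)
}

# A tiny in-memory tagged corpus + embedding table for tagger tests.
tiny_training_setup <- function(n_docs = 20L, noise = 0.1, seed = 3L,
                                spd = c(4L, 6L)) {
  cfg <- generator_config(n_documents = n_docs, sentences_per_document = spd,
                          transition_noise_rate = noise, seed = seed)
  corp <- generate_corpus(cfg)
  tagged <- documents_to_tagged(corp$documents)
  vocab <- build_vocabularies(tagged$sentences)
  ef <- tempfile(fileext = ".txt")
  write_word2vec(corp$embedding$words, corp$embedding$vectors, ef)
  emb <- load_embeddings(ef, vocab$words, seed = seed)
  list(corpus = corp, tagged = tagged, vocab = vocab, embeddings = emb,
       embedding_path = ef)
}
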