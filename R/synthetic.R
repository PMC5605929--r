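# Synthetic annotated-review generator. Produces corpora with the
# statistical structure the tagger assumes -- templated patient-review
# sentences carrying 0-4 multi-word ADR phrases from a fixed lexicon, with
# exact gold character offsets, optional overlapping raw annotations, and a
# matching toy word2vec embedding file -- so the full pipeline is testable
# without any external corpus.

#' Default ADR phrase lexicon
#'
#' About sixty 1--4-token adverse-reaction surface forms as patients write
#' them in drug reviews (headaches, weight gain, shortness of breath, ...).
#'
#' @return character vector of lowercase phrases.
#' @export
default_adr_lexicon <- function() c(
  "anxiety", "depression", "panic attacks", "weight gain", "nausea",
  "headaches", "dizziness", "insomnia", "mood swings", "dry mouth",
  "sweating", "rash", "heartburn", "severe nausea", "cramping",
  "neck pain", "twitching", "fever", "erectile dysfunction",
  "pins and needles", "burning sensations", "loose bowels", "night sweat",
  "chest pressure", "blisters", "jaw pain", "frequent headaches",
  "stomach pains", "severe dizziness", "nervous breakdown",
  "aches and pains", "swelling", "muscle aches", "profuse sweating",
  "indigestion", "ringing in my ears", "spasms", "trouble urinating",
  "palpitations", "cough", "dry cough", "fatigue", "hair loss",
  "shortness of breath", "tiredness", "diarrhea", "chest pain",
  "joint pain", "very tired", "light headed", "blurred vision",
  "heart palpitations", "hives", "hot flashes", "nightmares",
  "weight loss", "blurry vision", "stomach pain", "numbness",
  "constipation", "vomiting", "drowsiness", "vertigo", "tremors",
  "itching", "upset stomach")

default_templates <- function() list(
  c("i", "experienced", "{ADR}", "and", "{ADR}", "after", "two", "days"),
  c("this", "drug", "gave", "me", "{ADR}", "within", "a", "week"),
  c("no", "side", "effects", "so", "far", "and", "it", "works", "well"),
  c("after", "the", "first", "dose", "i", "had", "{ADR}", "then", "{ADR}",
    "and", "{ADR}"),
  c("my", "doctor", "said", "the", "{ADR}", "would", "fade", "soon"),
  c("been", "on", "it", "for", "months", "now", "with", "{ADR}"),
  c("started", "having", "{ADR}", "{ADR}", "and", "{ADR}", "almost",
    "immediately"),
  c("it", "helped", "my", "condition", "quite", "a", "lot"),
  c("i", "stopped", "taking", "it", "because", "of", "{ADR}", "and",
    "{ADR}"),
  c("worst", "experience", "ever", "with", "{ADR}", "{ADR}", "{ADR}",
    "and", "{ADR}"))

default_fillers <- function() c(
  "nothing unusual", "no problems", "some minor issues", "a better mood",
  "good results", "steady progress", "a clear head", "normal sleep")

#' Generator configuration
#'
#' Defaults define the package's reference study conditions: 250 documents
#' of 10 sentences each (2500 sentences, so a 0.8 document split gives
#' 2000 train / 500 test sentences), ADR phrases planted in 70% of template
#' slots, and a mild rate of "noise" carrier tokens -- single-token lexicon
#' words used in a non-ADR sense -- so that context matters and a pure
#' lexicon lookup cannot reach perfect precision.
#'
#' @param n_documents number of documents.
#' @param sentences_per_document length-2 integer range (inclusive).
#' @param adr_lexicon phrases (1--4 lowercase tokens each) planted as gold
#'   ADR spans.
#' @param carrier_templates list of token templates with \code{"{ADR}"}
#'   slots.
#' @param fillers non-ADR phrases used for unfilled slots.
#' @param p_adr_per_slot probability a slot receives an ADR phrase.
#' @param overlap_injection_rate fraction of gold spans that receive an
#'   overlapping raw duplicate via [inject_overlaps()] (0 = clean corpus).
#' @param embedding_dim toy embedding dimensionality.
#' @param embedding_coverage fraction of the generated vocabulary present in
#'   the emitted embedding file (the rest exercises OOV initialization).
#' @param transition_noise_rate probability a carrier token is replaced by a
#'   single-token lexicon word, unannotated.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_documents = 250L,
                             sentences_per_document = c(10L, 10L),
                             adr_lexicon = default_adr_lexicon(),
                             carrier_templates = default_templates(),
                             fillers = default_fillers(),
                             p_adr_per_slot = 0.7,
                             overlap_injection_rate = 0,
                             embedding_dim = 25L,
                             embedding_coverage = 0.97,
                             transition_noise_rate = 0.1,
                             seed = 13L) {
  stopifnot(length(adr_lexicon) > 0,
            p_adr_per_slot >= 0, p_adr_per_slot <= 1,
            overlap_injection_rate >= 0, overlap_injection_rate <= 1,
            transition_noise_rate >= 0, transition_noise_rate <= 1,
            length(sentences_per_document) == 2)
  structure(list(n_documents = as.integer(n_documents),
                 sentences_per_document = as.integer(sentences_per_document),
                 adr_lexicon = adr_lexicon,
                 carrier_templates = carrier_templates, fillers = fillers,
                 p_adr_per_slot = p_adr_per_slot,
                 overlap_injection_rate = overlap_injection_rate,
                 embedding_dim = as.integer(embedding_dim),
                 embedding_coverage = embedding_coverage,
                 transition_noise_rate = transition_noise_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Expected fraction of sentences containing at least one ADR span
#'
#' Closed-form expectation under the generative model: templates are drawn
#' uniformly and each slot is filled independently with probability
#' \code{p}, so the rate is \code{mean(1 - (1 - p)^slots)} over templates.
#'
#' @param config a [generator_config()].
#' @return scalar probability.
#' @export
expected_adr_sentence_rate <- function(config) {
  slots <- vapply(config$carrier_templates,
                  function(tp) sum(tp == "{ADR}"), integer(1))
  mean(1 - (1 - config$p_adr_per_slot)^slots)
}

#' Generate a synthetic annotated corpus
#'
#' Builds documents sentence by sentence from the carrier templates: each
#' \code{"{ADR}"} slot receives a lexicon phrase (recorded as a gold span
#' with exact character offsets) with probability \code{p_adr_per_slot} and
#' a neutral filler phrase otherwise; each carrier token is replaced by an
#' unannotated single-token lexicon word with probability
#' \code{transition_noise_rate}. Sentences end with a period token and
#' documents join sentences with spaces, so the package tokenizer recovers
#' the construction exactly. Also builds a toy embedding table covering
#' \code{embedding_coverage} of the generated vocabulary. Byte-identical
#' output for a given seed. If \code{overlap_injection_rate > 0}, raw
#' overlapping annotations are added via [inject_overlaps()].
#'
#' @param config a [generator_config()].
#' @return list with \code{documents} (list of [adr_document()]),
#'   \code{embedding} (list \code{words}/\code{vectors}), and
#'   \code{config}.
#' @export
generate_corpus <- function(config = generator_config()) {
  lex_tokens <- strsplit(config$adr_lexicon, " ", fixed = TRUE)
  single_tok <- config$adr_lexicon[lengths(lex_tokens) == 1L]
  if (length(single_tok) == 0) single_tok <- config$adr_lexicon[1]
  out <- with_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    for (di in seq_len(config$n_documents)) {
      rng <- config$sentences_per_document
      ns <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
      pieces <- character()
      pos <- 0L
      starts <- integer(); ends <- integer()
      push <- function(tok) {
        if (pos > 0L) { pieces <<- c(pieces, " "); pos <<- pos + 1L }
        pieces <<- c(pieces, tok)
        s <- pos
        pos <<- pos + nchar(tok)
        c(s, pos)
      }
      for (si in seq_len(ns)) {
        tp <- config$carrier_templates[[
          sample.int(length(config$carrier_templates), 1L)]]
        for (tok in tp) {
          if (tok == "{ADR}") {
            if (stats::runif(1) < config$p_adr_per_slot) {
              phrase <- config$adr_lexicon[
                sample.int(length(config$adr_lexicon), 1L)]
              ph_toks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
              se <- push(ph_toks[1])
              sp_start <- se[1]
              for (w in ph_toks[-1]) se <- push(w)
              starts <- c(starts, sp_start); ends <- c(ends, se[2])
            } else {
              filler <- config$fillers[sample.int(length(config$fillers), 1L)]
              for (w in strsplit(filler, " ", fixed = TRUE)[[1]]) push(w)
            }
          } else {
            w <- tok
            if (stats::runif(1) < config$transition_noise_rate)
              w <- single_tok[sample.int(length(single_tok), 1L)]
            push(w)
          }
        }
        push(".")
      }
      text <- paste(pieces, collapse = "")
      docs[[di]] <- adr_document(sprintf("synth_%04d", di), text,
                                 entity_spans(starts, ends, "ADR",
                                              span_text(text, starts, ends)))
    }
    vocab <- sort(unique(unlist(lapply(docs, function(d)
      tokenize_text(d$text)$surface))))
    n_cov <- max(1L, floor(config$embedding_coverage * length(vocab)))
    covered <- sort(sample(vocab, n_cov))
    vecs <- matrix(stats::runif(n_cov * config$embedding_dim, -0.5, 0.5),
                   n_cov, config$embedding_dim)
    rownames(vecs) <- covered
    list(documents = docs, embedding = list(words = covered, vectors = vecs))
  })
  if (config$overlap_injection_rate > 0)
    out$documents <- inject_overlaps(out$documents,
                                     config$overlap_injection_rate,
                                     config$seed + 1L)
  out$config <- config
  out
}

#' Inject overlapping raw annotations
#'
#' For each gold span selected with probability \code{rate}, adds a second
#' raw span overlapping it -- a sub-span dropping the first token for
#' multi-token spans, otherwise an extension over the following carrier
#' token -- so that [resolve_overlaps()] has real work to do. The expected
#' post-resolution span set of each document is recorded in its
#' \code{expected_spans} element for oracle checks. Injection never creates
#' overlap with a neighbouring gold span (such candidates fall back to the
#' other variant or are skipped).
#'
#' @param documents list of [adr_document()]s.
#' @param rate probability of injecting per gold span.
#' @param seed integer seed.
#' @return documents with possibly duplicated raw spans and an
#'   \code{expected_spans} table each.
#' @export
inject_overlaps <- function(documents, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, lapply(documents, function(doc) {
    sp <- doc$spans
    toks <- tokenize_text(doc$text)
    exp_s <- sp$start; exp_e <- sp$end
    add_s <- integer(); add_e <- integer()
    tok_free <- function(j, i) {
      j >= 1 && j <= nrow(toks) && toks$surface[j] != "." &&
        !any(sp$start[-i] < toks$end[j] & sp$end[-i] > toks$start[j])
    }
    for (i in seq_len(nrow(sp))) {
      if (stats::runif(1) >= rate) next
      inside <- which(toks$start >= sp$start[i] & toks$end <= sp$end[i])
      if (length(inside) >= 2) {        # sub-span: drop the first token
        add_s <- c(add_s, toks$start[inside[2]])
        add_e <- c(add_e, sp$end[i])
        next
      }
      nxt <- which(toks$start >= sp$end[i])[1]   # suffix extension
      if (!is.na(nxt) && tok_free(nxt, i)) {
        add_s <- c(add_s, sp$start[i])
        add_e <- c(add_e, toks$end[nxt])
        exp_e[i] <- toks$end[nxt]
        next
      }
      prv <- rev(which(toks$end <= sp$start[i]))[1]  # prefix extension
      if (!is.na(prv) && tok_free(prv, i)) {
        add_s <- c(add_s, toks$start[prv])
        add_e <- c(add_e, sp$end[i])
        exp_s[i] <- toks$start[prv]
      }
    }
    all_sp <- entity_spans(c(sp$start, add_s), c(sp$end, add_e), "ADR",
                           span_text(doc$text, c(sp$start, add_s),
                                     c(sp$end, add_e)))
    out <- adr_document(doc$doc_id, doc$text, all_sp)
    out$expected_spans <- resolve_overlaps(
      entity_spans(exp_s, exp_e, "ADR"), doc$text)
    out
  }))
}

#' Lexicon-lookup baseline tagger
#'
#' Labels every greedy longest match of a lexicon phrase in a sentence as a
#' predicted ADR span. On generated corpora this recalls every gold span by
#' construction, but when carrier noise plants lexicon words in non-ADR
#' positions its precision drops below 1 -- the learning task is not
#' solvable by lookup alone.
#'
#' @param sentences list of \code{adr_sentence}s.
#' @param lexicon character vector of phrases.
#' @return list of span tables.
#' @export
lexicon_baseline <- function(sentences, lexicon = default_adr_lexicon()) {
  lex <- strsplit(tolower(lexicon), " ", fixed = TRUE)
  max_len <- max(lengths(lex))
  keys <- vapply(lex, paste, character(1), collapse = " ")
  lapply(sentences, function(s) {
    surf <- tolower(s$tokens$surface)
    n <- length(surf)
    starts <- integer(); ends <- integer()
    i <- 1L
    while (i <= n) {
      matched <- 0L
      for (L in min(max_len, n - i + 1L):1) {
        if (paste(surf[i:(i + L - 1L)], collapse = " ") %in% keys) {
          matched <- L; break
        }
      }
      if (matched > 0L) {
        starts <- c(starts, s$tokens$start[i])
        ends <- c(ends, s$tokens$end[i + matched - 1L])
        i <- i + matched
      } else i <- i + 1L
    }
    entity_spans(starts, ends, "ADR")
  })
}
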