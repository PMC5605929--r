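# The joint tagger: word embeddings (+) char-CNN features -> stacked
# bidirectional GRU/LSTM -> dropout -> linear dense layer -> per-token tag
# scores, decoded either with a per-token softmax head or with a
# linear-chain CRF head trained by exact NLL. Training is mini-batch Adam
# over padded batches with length masks.

ADR_TAGSET <- c("O", "B-ADR", "I-ADR")   # O first so score ties decode to O

#' Tagger configuration
#'
#' @param cell recurrent cell, \code{"gru"} or \code{"lstm"}.
#' @param num_layers number of stacked bidirectional layers (1--4).
#' @param hidden_size hidden units per direction.
#' @param dropout dropout rate applied to the recurrent output before the
#'   dense layer (the only dropout site), in \code{[0, 1)}.
#' @param use_char_cnn concatenate character-CNN features to the word
#'   embedding.
#' @param head \code{"crf"} (joint model) or \code{"softmax"} (baseline).
#' @param batch_size mini-batch size (default 128).
#' @param max_epochs training epoch budget (default 100).
#' @param lr Adam learning rate; remaining Adam parameters are the defaults.
#' @param seed single integer controlling parameter initialization, OOV
#'   embedding draws and batch shuffling.
#' @param char_dim,filter_widths,filters_per_width,max_word_length char-CNN
#'   geometry; see [char_cnn_config()].
#' @param trainable_embeddings update word embeddings during training.
#' @return list of class \code{tagger_config}.
#' @export
tagger_config <- function(cell = c("gru", "lstm"), num_layers = 2L,
                          hidden_size = 100L, dropout = 0.5,
                          use_char_cnn = TRUE, head = c("crf", "softmax"),
                          batch_size = 128L, max_epochs = 100L, lr = 1e-3,
                          seed = 1L, char_dim = 25L,
                          filter_widths = c(2L, 3L, 4L),
                          filters_per_width = 25L, max_word_length = 20L,
                          trainable_embeddings = TRUE) {
  cell <- match.arg(cell)
  head <- match.arg(head)
  if (!num_layers %in% 1:4) stop("num_layers must be in 1..4")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(cell = cell, num_layers = as.integer(num_layers),
                 hidden_size = as.integer(hidden_size), dropout = dropout,
                 use_char_cnn = isTRUE(use_char_cnn), head = head,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 seed = as.integer(seed), char_dim = as.integer(char_dim),
                 filter_widths = as.integer(filter_widths),
                 filters_per_width = as.integer(filters_per_width),
                 max_word_length = as.integer(max_word_length),
                 trainable_embeddings = isTRUE(trainable_embeddings)),
            class = "tagger_config")
}

#' Build word and character vocabularies from sentences
#'
#' Words are lowercased for the embedding lookup; characters keep their
#' case so the char-CNN retains shape information the lookup discards.
#' Both vocabularies include an \code{"<unk>"} fallback.
#'
#' @param sentences list of \code{adr_sentence}s.
#' @return list with \code{words} and \code{chars} character vectors.
#' @export
build_vocabularies <- function(sentences) {
  surf <- unlist(lapply(sentences, function(s) s$tokens$surface))
  words <- sort(unique(tolower(surf)))
  chars <- sort(unique(unlist(strsplit(surf, ""))))
  list(words = c("<unk>", words), chars = c("<unk>", chars))
}

#' Initialize an untrained tagger model
#'
#' @param config a [tagger_config()].
#' @param embeddings an \code{embedding_table} (from [load_embeddings()])
#'   whose vocabulary includes \code{"<unk>"}.
#' @param char_vocabulary character vector including \code{"<unk>"}; required
#'   when \code{config$use_char_cnn}.
#' @param init \code{"glorot"} (default) or \code{"zero"} (all recurrent,
#'   convolutional and dense weights zero -- useful for contracts/tests).
#' @return object of class \code{adr_tagger}.
#' @export
tagger_init <- function(config, embeddings, char_vocabulary = NULL,
                        init = c("glorot", "zero")) {
  init <- match.arg(init)
  stopifnot(inherits(config, "tagger_config"))
  if (!"<unk>" %in% names(embeddings$vocabulary))
    stop("embedding vocabulary must include \"<unk>\"")
  k <- length(ADR_TAGSET)
  d_word <- ncol(embeddings$vectors)
  cnn_cfg <- NULL
  f_dim <- 0L
  params <- list(E = embeddings$vectors)
  build <- function() {
    if (config$use_char_cnn) {
      ch <- stats::setNames(seq_along(char_vocabulary), char_vocabulary)
      cnn_cfg <<- char_cnn_config(ch, config$char_dim, config$filter_widths,
                                  config$filters_per_width,
                                  config$max_word_length)
      params <<- c(params, char_cnn_init(cnn_cfg))
      f_dim <<- length(config$filter_widths) * config$filters_per_width
    }
    h <- config$hidden_size
    for (l in seq_len(config$num_layers)) {
      d_in <- if (l == 1) d_word + f_dim else 2L * h
      for (dir in c("f", "b")) {
        p <- rnn_init(config$cell, d_in, h)
        params[[sprintf("rnnW_l%d_%s", l, dir)]] <<- p$W
        params[[sprintf("rnnU_l%d_%s", l, dir)]] <<- p$U
        params[[sprintf("rnnb_l%d_%s", l, dir)]] <<- p$b
      }
    }
    params$Wout <<- glorot(2L * h, k)
    params$bout <<- numeric(k)
    if (config$head == "crf") {
      params$trans <<- matrix(0, k, k)
      params$start <<- numeric(k)
      params$stop <<- numeric(k)
    }
  }
  if (config$use_char_cnn && is.null(char_vocabulary))
    stop("char_vocabulary required when use_char_cnn = TRUE")
  with_seed(config$seed, build())
  if (init == "zero") {
    zero_keep <- c("E", "trans", "start", "stop")
    for (nm in setdiff(names(params), zero_keep)) params[[nm]] <- params[[nm]] * 0
    if (config$head == "crf") {
      params$trans <- params$trans * 0
      params$start <- params$start * 0
      params$stop <- params$stop * 0
    }
  }
  structure(list(config = config, cnn_config = cnn_cfg, params = params,
                 tagset = ADR_TAGSET,
                 word_index = embeddings$vocabulary,
                 history = NULL),
            class = "adr_tagger")
}

#' @export
print.adr_tagger <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<adr_tagger: %d-layer bi%s%s + %s head, %d parameters>\n",
              cfg$num_layers, toupper(cfg$cell),
              if (cfg$use_char_cnn) " + char-CNN" else "",
              cfg$head, np))
  invisible(x)
}

# ---- batched forward / backward --------------------------------------------

# Forward pass over a batch of sentences. Returns tag scores [B, T, |Y|]
# plus everything backward needs when training = TRUE.
encode_batch <- function(model, sentences, training = FALSE) {
  cfg <- model$config
  prm <- model$params
  B <- length(sentences)
  lens <- vapply(sentences, function(s) nrow(s$tokens), integer(1))
  if (any(lens == 0)) stop("cannot encode an empty sentence")
  Tm <- max(lens)
  k <- length(model$tagset)
  unk <- model$word_index[["<unk>"]]
  ids <- matrix(unk, B, Tm)
  mask <- matrix(0, B, Tm)
  surf <- matrix(NA_character_, B, Tm)
  for (b in seq_len(B)) {
    lo <- tolower(sentences[[b]]$tokens$surface)
    id <- model$word_index[lo]
    id[is.na(id)] <- unk
    n <- lens[b]
    ids[b, seq_len(n)] <- id
    mask[b, seq_len(n)] <- 1
    surf[b, seq_len(n)] <- sentences[[b]]$tokens$surface
  }
  d_word <- ncol(prm$E)
  flat_n <- B * Tm
  Xw <- prm$E[as.vector(ids), , drop = FALSE]      # (B*T) x d, (b,t) major
  char <- NULL
  if (cfg$use_char_cnn) {
    sel <- as.vector(mask) == 1
    types <- unique(as.vector(surf)[sel])
    f_dim <- length(cfg$filter_widths) * cfg$filters_per_width
    feats <- matrix(0, length(types), f_dim)
    caches <- if (training) vector("list", length(types)) else NULL
    for (i in seq_along(types)) {
      fv <- char_features(types[i], model$cnn_config, prm, cache = training)
      feats[i, ] <- fv
      if (training) caches[[i]] <- attr(fv, "cache")
    }
    type_idx <- match(as.vector(surf), types)      # NA at padding
    Xc <- matrix(0, flat_n, f_dim)
    Xc[sel, ] <- feats[type_idx[sel], , drop = FALSE]
    X_flat <- cbind(Xw, Xc)
    char <- list(types = types, caches = caches, type_idx = type_idx,
                 sel = sel, f_dim = f_dim)
  } else {
    X_flat <- Xw
  }
  d0 <- ncol(X_flat)
  inputs <- vector("list", cfg$num_layers + 1L)
  inputs[[1]] <- array(X_flat, c(B, Tm, d0))
  fwds <- vector("list", cfg$num_layers)
  h <- cfg$hidden_size
  for (l in seq_len(cfg$num_layers)) {
    ff <- rnn_forward(inputs[[l]], mask, prm[[sprintf("rnnW_l%d_f", l)]],
                      prm[[sprintf("rnnU_l%d_f", l)]],
                      prm[[sprintf("rnnb_l%d_f", l)]], cfg$cell, FALSE)
    fb <- rnn_forward(inputs[[l]], mask, prm[[sprintf("rnnW_l%d_b", l)]],
                      prm[[sprintf("rnnU_l%d_b", l)]],
                      prm[[sprintf("rnnb_l%d_b", l)]], cfg$cell, TRUE)
    fwds[[l]] <- list(f = ff, b = fb)
    Hcat <- cbind(matrix(ff$H, flat_n, h), matrix(fb$H, flat_n, h))
    inputs[[l + 1]] <- array(Hcat, c(B, Tm, 2L * h))
  }
  top_flat <- matrix(inputs[[cfg$num_layers + 1L]], flat_n, 2L * h)
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    drop_mask <- matrix(
      (stats::runif(flat_n * 2L * h) >= cfg$dropout) / (1 - cfg$dropout),
      flat_n, 2L * h)
    top_flat <- top_flat * drop_mask
  }
  S_flat <- sweep(top_flat %*% prm$Wout, 2L, prm$bout, "+")
  list(S = array(S_flat, c(B, Tm, k)), lens = lens, mask = mask,
       cache = if (training) list(ids = ids, char = char, inputs = inputs,
                                  fwds = fwds, drop_mask = drop_mask,
                                  top_flat = top_flat, B = B, Tm = Tm)
       else NULL)
}

# Backward pass: dS is the [B, T, |Y|] gradient of the loss w.r.t. the tag
# scores (already zero at padded positions). Returns gradients for every
# trainable parameter.
backward_batch <- function(model, enc, dS) {
  cfg <- model$config
  prm <- model$params
  cc <- enc$cache
  B <- cc$B; Tm <- cc$Tm
  flat_n <- B * Tm
  h <- cfg$hidden_size
  grads <- list()
  dS_flat <- matrix(dS, flat_n, length(model$tagset))
  grads$Wout <- crossprod(cc$top_flat, dS_flat)
  grads$bout <- colSums(dS_flat)
  dH_flat <- dS_flat %*% t(prm$Wout)
  if (!is.null(cc$drop_mask)) dH_flat <- dH_flat * cc$drop_mask
  dH <- array(dH_flat, c(B, Tm, 2L * h))
  for (l in cfg$num_layers:1) {
    dHf <- dH[, , seq_len(h), drop = FALSE]
    dHb <- dH[, , h + seq_len(h), drop = FALSE]
    dim(dHf) <- c(B, Tm, h); dim(dHb) <- c(B, Tm, h)
    bf <- rnn_backward(cc$inputs[[l]], enc$mask,
                       prm[[sprintf("rnnW_l%d_f", l)]],
                       prm[[sprintf("rnnU_l%d_f", l)]],
                       prm[[sprintf("rnnb_l%d_f", l)]],
                       cfg$cell, FALSE, cc$fwds[[l]]$f, dHf)
    bb <- rnn_backward(cc$inputs[[l]], enc$mask,
                       prm[[sprintf("rnnW_l%d_b", l)]],
                       prm[[sprintf("rnnU_l%d_b", l)]],
                       prm[[sprintf("rnnb_l%d_b", l)]],
                       cfg$cell, TRUE, cc$fwds[[l]]$b, dHb)
    grads[[sprintf("rnnW_l%d_f", l)]] <- bf$dW
    grads[[sprintf("rnnU_l%d_f", l)]] <- bf$dU
    grads[[sprintf("rnnb_l%d_f", l)]] <- bf$db
    grads[[sprintf("rnnW_l%d_b", l)]] <- bb$dW
    grads[[sprintf("rnnU_l%d_b", l)]] <- bb$dU
    grads[[sprintf("rnnb_l%d_b", l)]] <- bb$db
    dX <- bf$dx + bb$dx
    if (l > 1) dH <- dX
    else {
      d_word <- ncol(prm$E)
      dX_flat <- matrix(dX, flat_n, dim(dX)[3])
      if (cfg$trainable_embeddings) {
        dXw <- dX_flat[, seq_len(d_word), drop = FALSE]
        agg <- rowsum(dXw, group = as.vector(cc$ids))
        dE <- matrix(0, nrow(prm$E), d_word)
        dE[as.integer(rownames(agg)), ] <- agg
        grads$E <- dE
      }
      if (cfg$use_char_cnn) {
        ch <- cc$char
        dXc <- dX_flat[ch$sel, d_word + seq_len(ch$f_dim), drop = FALSE]
        agg <- rowsum(dXc, group = ch$type_idx[ch$sel])
        cg <- list(C = prm$C * 0)
        for (w in cfg$filter_widths) {
          cg[[sprintf("convW_w%d", w)]] <- prm[[sprintf("convW_w%d", w)]] * 0
          cg[[sprintf("convb_w%d", w)]] <- prm[[sprintf("convb_w%d", w)]] * 0
        }
        rows <- as.integer(rownames(agg))
        for (j in seq_along(rows))
          cg <- char_features_backward(agg[j, ], model$cnn_config, prm,
                                       ch$caches[[rows[j]]], cg)
        grads <- c(grads, cg)
      }
    }
  }
  grads
}

# Loss + dS for one batch under the configured head. gold is a B x T matrix
# of tag indices. Returns list(loss, dS, extra_grads).
batch_loss <- function(model, enc, gold) {
  cfg <- model$config
  B <- dim(enc$S)[1]
  if (cfg$head == "crf") {
    res <- crf_batch_nll_grad(enc$S, enc$lens, model$params$trans,
                              model$params$start, model$params$stop, gold)
    list(loss = res$nll / B, dS = res$unary / B,
         extra = list(trans = res$transitions / B, start = res$start / B,
                      stop = res$stop / B))
  } else {
    k <- dim(enc$S)[3]
    Tm <- dim(enc$S)[2]
    S_flat <- matrix(enc$S, B * Tm, k)
    mx <- apply(S_flat, 1L, max)
    ex <- exp(S_flat - mx)
    p <- ex / rowSums(ex)
    sel <- as.vector(enc$mask) == 1
    gold_flat <- as.vector(gold)
    rows <- which(sel)
    loss <- -sum(log(pmax(p[cbind(rows, gold_flat[rows])], 1e-300))) / B
    dS_flat <- p
    dS_flat[cbind(rows, gold_flat[rows])] <-
      dS_flat[cbind(rows, gold_flat[rows])] - 1
    dS_flat[!sel, ] <- 0
    list(loss = loss, dS = array(dS_flat / B, dim(enc$S)), extra = NULL)
  }
}

# ---- training ---------------------------------------------------------------

tags_to_indices <- function(tags, tagset) {
  idx <- match(tags, tagset)
  if (anyNA(idx)) stop("unknown tag(s): ",
                       paste(unique(tags[is.na(idx)]), collapse = ", "))
  idx
}

#' Train a tagger
#'
#' Minimizes the CRF negative log-likelihood (crf head) or per-token
#' cross-entropy (softmax head) by mini-batch Adam with default parameters.
#' Sentences are shuffled every epoch; batches are padded with explicit
#' length masks so padding contributes nothing to loss or gradients. When a
#' dev corpus is given, exact-match F1 is computed after every epoch and the
#' best-scoring parameters are returned (fixed epoch budget, no early
#' stopping). All randomness flows from \code{config$seed}.
#'
#' @param train,dev tagged corpora: lists with \code{sentences} (list of
#'   \code{adr_sentence}) and \code{tags} (parallel list of BIO tag
#'   vectors); \code{dev} may be \code{NULL}.
#' @param config a [tagger_config()].
#' @param embeddings an \code{embedding_table} covering the training
#'   vocabulary (plus \code{"<unk>"}).
#' @param verbose print a key=value log line per epoch.
#' @return trained \code{adr_tagger} with a \code{history} data.frame
#'   (epoch, loss, dev precision/recall/F1).
#' @export
train_tagger <- function(train, dev = NULL, config, embeddings,
                         verbose = FALSE) {
  if (length(train$sentences) == 0) stop("empty training corpus")
  stopifnot(length(train$sentences) == length(train$tags))
  vocab <- build_vocabularies(train$sentences)
  model <- tagger_init(config, embeddings,
                       char_vocabulary = if (config$use_char_cnn) vocab$chars)
  gold_idx <- lapply(train$tags, tags_to_indices, tagset = model$tagset)
  n <- length(train$sentences)
  state <- adam_init(model$params)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     dev_precision = numeric(), dev_recall = numeric(),
                     dev_f1 = numeric())
  best <- list(f1 = -Inf, params = model$params)
  # the braces evaluate lazily in this frame, so assignments below update
  # train_tagger's locals while the RNG is pinned to config$seed
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(n)
      losses <- numeric()
      for (s0 in seq(1L, n, by = config$batch_size)) {
        bi <- perm[s0:min(s0 + config$batch_size - 1L, n)]
        sents <- train$sentences[bi]
        enc <- encode_batch(model, sents, training = TRUE)
        gold <- matrix(1L, length(bi), max(enc$lens))
        for (j in seq_along(bi))
          gold[j, seq_len(enc$lens[j])] <- gold_idx[[bi[j]]]
        bl <- batch_loss(model, enc, gold)
        grads <- backward_batch(model, enc, bl$dS)
        if (!is.null(bl$extra)) grads <- c(grads, bl$extra)
        upd <- adam_step(model$params, grads, state, lr = config$lr)
        model$params <- upd$params
        state <- upd$state
        losses <- c(losses, bl$loss)
      }
      dev_p <- NA_real_; dev_r <- NA_real_; dev_f <- NA_real_
      if (!is.null(dev)) {
        rep_ <- evaluate_tagger(model, dev, mode = "exact")
        dev_p <- rep_$precision; dev_r <- rep_$recall; dev_f <- rep_$f1
        if (dev_f > best$f1) best <- list(f1 = dev_f, params = model$params)
      }
      hist[nrow(hist) + 1L, ] <- list(epoch, mean(losses), dev_p, dev_r, dev_f)
      if (verbose)
        message(sprintf("epoch=%d loss=%.4f dev_p=%.4f dev_r=%.4f dev_f=%.4f",
                        epoch, mean(losses), dev_p, dev_r, dev_f))
    }
  })
  if (!is.null(dev) && is.finite(best$f1)) model$params <- best$params
  model$history <- hist
  model
}

# ---- prediction -------------------------------------------------------------

#' Per-token tag scores for one sentence
#'
#' Evaluation-mode (deterministic, no dropout) forward pass producing the
#' n x |Y| unary score matrix the decoder consumes.
#'
#' @param model trained or initialized \code{adr_tagger}.
#' @param sentence an \code{adr_sentence}.
#' @return n x |Y| matrix with tagset column names.
#' @export
encode_sentence <- function(model, sentence) {
  enc <- encode_batch(model, list(sentence), training = FALSE)
  m <- matrix(enc$S[1, , ], dim(enc$S)[2], dim(enc$S)[3])
  m <- m[seq_len(enc$lens[1]), , drop = FALSE]
  colnames(m) <- model$tagset
  m
}

# Decode tag index sequences for a list of sentences.
predict_tag_indices <- function(model, sentences, constrained = FALSE) {
  cfg <- model$config
  out <- vector("list", length(sentences))
  forb <- if (constrained) bio_forbidden(model$tagset)
  for (s0 in seq(1L, length(sentences), by = cfg$batch_size)) {
    bi <- s0:min(s0 + cfg$batch_size - 1L, length(sentences))
    enc <- encode_batch(model, sentences[bi], training = FALSE)
    for (j in seq_along(bi)) {
      n <- enc$lens[j]
      u <- matrix(enc$S[j, seq_len(n), ], n, length(model$tagset))
      if (cfg$head == "crf") {
        lat <- score_lattice(u, model$params$trans, model$params$start,
                             model$params$stop)
        res <- if (constrained) crf_constrained_viterbi(lat, forb)
               else crf_viterbi(lat)
        out[[bi[j]]] <- res$path
      } else {
        if (constrained) {
          lat <- score_lattice(u)   # zero transitions: positionwise argmax
          out[[bi[j]]] <- crf_constrained_viterbi(lat, forb)$path
        } else {
          out[[bi[j]]] <- max.col(u, ties.method = "first")
        }
      }
    }
  }
  out
}

#' Predict ADR spans for sentences
#'
#' Encodes each sentence, decodes tags (Viterbi for the crf head,
#' per-position argmax for the softmax head), and converts the BIO sequence
#' to character-offset spans. Softmax heads can emit orphan \code{I-} tags;
#' these are repaired during span decoding. Deterministic.
#'
#' @param model trained \code{adr_tagger}.
#' @param sentences list of \code{adr_sentence}s.
#' @param constrained forbid BIO-invalid transitions at decode time.
#' @return list of span tables, one per sentence.
#' @export
predict_tagger <- function(model, sentences, constrained = FALSE) {
  idx <- predict_tag_indices(model, sentences, constrained)
  lapply(seq_along(sentences), function(i)
    bio_to_spans(sentences[[i]], model$tagset[idx[[i]]], mode = "repair"))
}

#' Evaluate a tagger on a tagged corpus
#'
#' Predicts spans for the corpus sentences and scores them against the gold
#' BIO tags under the requested matching mode.
#'
#' @param model trained \code{adr_tagger}.
#' @param corpus tagged corpus (\code{sentences} + \code{tags}).
#' @param mode \code{"exact"} or \code{"partial"}.
#' @param ... passed to [evaluate_corpus()].
#' @return an \code{eval_report}.
#' @export
evaluate_tagger <- function(model, corpus, mode = "exact", ...) {
  pred_spans <- predict_tagger(model, corpus$sentences)
  gold_spans <- lapply(seq_along(corpus$sentences), function(i)
    bio_to_spans(corpus$sentences[[i]], corpus$tags[[i]]))
  gold_terms <- lapply(seq_along(gold_spans), function(i)
    spans_to_terms(corpus$sentences[[i]], gold_spans[[i]]))
  pred_terms <- lapply(seq_along(pred_spans), function(i)
    spans_to_terms(corpus$sentences[[i]], pred_spans[[i]]))
  evaluate_corpus(gold_terms, pred_terms, mode = mode, ...)
}

# ---- corpus preparation and checkpoints ------------------------------------

#' Convert annotated documents to a tagged corpus
#'
#' Resolves overlapping ADR spans, splits each document into sentences, and
#' projects the resolved spans to BIO tags.
#'
#' @param documents list of [adr_document()]s.
#' @param label keep only spans with this label before resolution
#'   (default \code{"ADR"}; NULL keeps all).
#' @return list with \code{sentences} and \code{tags}.
#' @export
documents_to_tagged <- function(documents, label = "ADR") {
  sentences <- list(); tags <- list()
  for (doc in documents) {
    sp <- doc$spans
    if (!is.null(label)) sp <- sp[sp$label %in% label, , drop = FALSE]
    sp <- resolve_overlaps(sp, doc$text)
    for (s in doc_sentences(doc)) {
      sentences[[length(sentences) + 1L]] <- s
      tags[[length(tags) + 1L]] <- spans_to_bio(s, sp)
    }
  }
  list(sentences = sentences, tags = tags)
}

#' Save / load a tagger checkpoint
#'
#' The checkpoint is a single RDS archive holding the config, tag
#' inventory, vocabularies and all parameter arrays.
#'
#' @param model an \code{adr_tagger}.
#' @param path checkpoint file path.
#' @return \code{load_tagger} returns the model.
#' @export
save_tagger <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  structure(readRDS(path), class = "adr_tagger")
}
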