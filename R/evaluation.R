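# Span evaluation: exact matching in the CoNLL style, and token-overlap
# ("partial") matching averaged per sentence.

#' Exact-match counts between gold and predicted spans
#'
#' A predicted span is a true positive only if its (start, end, label)
#' triple equals a gold span's exactly.
#'
#' @param gold,pred span tables (data.frames with \code{start}, \code{end},
#'   \code{label}).
#' @return list with \code{TP}, \code{FP}, \code{FN}.
#' @export
exact_counts <- function(gold, pred) {
  key <- function(sp) {
    if (nrow(sp) == 0) return(character())
    if (all(c("first", "last") %in% names(sp)))
      paste(sp$first, sp$last, sep = "|")
    else paste(sp$start, sp$end, sp$label, sep = "|")
  }
  g <- unique(key(gold)); p <- unique(key(pred))
  tp <- length(intersect(g, p))
  list(TP = tp, FP = length(p) - tp, FN = length(g) - tp)
}

#' Precision, recall and F1 from counts
#'
#' \code{P = TP/(TP+FP)}, \code{R = TP/(TP+FN)}, \code{F = 2PR/(P+R)}; any
#' zero denominator yields 0 by convention.
#'
#' @param counts list with \code{TP}, \code{FP}, \code{FN}.
#' @return named numeric vector \code{c(precision, recall, f1)}.
#' @export
prf <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# terms: data.frame(first, last) of 1-based inclusive token-index intervals
term_len <- function(terms) terms$last - terms$first + 1L

term_intersection <- function(a_first, a_last, b_first, b_last)
  pmax(0L, pmin(a_last, b_last) - pmax(a_first, b_first) + 1L)

#' Token-overlap (partial) precision and recall for one sentence
#'
#' For every (gold term t, predicted term t_s) pair that intersects,
#' precision credits |t intersect t_s| / |t_s| and recall credits
#' |t intersect t_s| / |t|, lengths measured in tokens; per-term credit is
#' capped at 1 so that multiple intersections cannot push a ratio above 1.
#' Totals are normalized by the number of predicted (P) and gold (R) terms.
#' Empty sides return \code{NA} for the corresponding ratio (0/0), which the
#' corpus-level averaging resolves by convention.
#'
#' @param gold,pred data.frames of token-index intervals with columns
#'   \code{first}, \code{last} (1-based, inclusive).
#' @return named numeric vector \code{c(precision, recall)}, possibly NA.
#' @export
partial_sentence <- function(gold, pred) {
  ng <- nrow(gold); np <- nrow(pred)
  p <- NA_real_; r <- NA_real_
  if (np > 0) {
    credit <- vapply(seq_len(np), function(i) {
      inter <- term_intersection(gold$first, gold$last,
                                 pred$first[i], pred$last[i])
      min(1, sum(inter) / (pred$last[i] - pred$first[i] + 1L))
    }, numeric(1))
    if (ng == 0) credit <- rep(0, np)
    p <- sum(credit) / np
  }
  if (ng > 0) {
    credit <- vapply(seq_len(ng), function(i) {
      inter <- term_intersection(pred$first, pred$last,
                                 gold$first[i], gold$last[i])
      min(1, sum(inter) / (gold$last[i] - gold$first[i] + 1L))
    }, numeric(1))
    if (np == 0) credit <- rep(0, ng)
    r <- sum(credit) / ng
  }
  c(precision = p, recall = r)
}

#' Project character spans to token-index terms
#'
#' Any token whose character interval intersects the span belongs to the
#' term (partial overlap counts). Spans touching no token are dropped.
#'
#' @param sentence an \code{adr_sentence}.
#' @param spans span table with character offsets.
#' @return data.frame of \code{first}/\code{last} token indices.
#' @export
spans_to_terms <- function(sentence, spans) {
  toks <- sentence$tokens
  first <- integer(); last <- integer()
  for (i in seq_len(nrow(spans))) {
    hit <- which(spans_overlap_token(toks$start, toks$end,
                                     spans$start[i], spans$end[i]))
    if (length(hit) == 0) next
    first <- c(first, hit[1]); last <- c(last, hit[length(hit)])
  }
  data.frame(first = first, last = last)
}

#' Evaluate predicted spans against gold over a corpus
#'
#' Inputs are parallel lists of per-sentence span tables (token-index terms
#' as produced by [spans_to_terms()], or anything with \code{first}/
#' \code{last} columns; for exact mode, \code{start}/\code{end}/\code{label}
#' span tables also work as long as gold and pred use the same coordinates).
#'
#' Exact mode pools counts over the corpus (CoNLL convention) and then
#' computes P/R/F; a per-sentence macro-averaged variant is available via
#' \code{macro_exact = TRUE}. Partial mode computes token-overlap P/R per
#' sentence and averages over sentences; F is the harmonic mean of the
#' averaged P and R.
#'
#' A sentence with neither gold nor predicted terms counts as handled
#' perfectly -- \code{(1, 1)} -- under \code{empty_sentence = "perfect"}
#' (default), or is dropped from both averages under \code{"skip"}. A
#' sentence with gold terms but no prediction contributes R = 0 and is
#' excluded from the P average (0/0); symmetrically for spurious-only
#' sentences.
#'
#' @param gold,pred parallel lists of per-sentence term/span tables.
#' @param mode \code{"exact"} or \code{"partial"}.
#' @param empty_sentence convention for sentences empty on both sides.
#' @param macro_exact average exact-mode P/R per sentence instead of pooling
#'   counts.
#' @return an \code{eval_report}: list with \code{mode}, \code{precision},
#'   \code{recall}, \code{f1}, and \code{per_sentence} (partial mode).
#' @export
evaluate_corpus <- function(gold, pred, mode = c("exact", "partial"),
                            empty_sentence = c("perfect", "skip"),
                            macro_exact = FALSE) {
  mode <- match.arg(mode)
  empty_sentence <- match.arg(empty_sentence)
  if (length(gold) != length(pred))
    stop("gold and pred must cover the same sentences (",
         length(gold), " vs ", length(pred), ")")
  if (mode == "exact") {
    if (macro_exact) {
      ps <- t(vapply(seq_along(gold), function(i)
        prf(exact_counts(gold[[i]], pred[[i]]))[1:2], numeric(2)))
      p <- mean(ps[, 1]); r <- mean(ps[, 2])
      f <- if (p + r > 0) 2 * p * r / (p + r) else 0
      rep_ <- list(mode = "exact", precision = p, recall = r, f1 = f)
    } else {
      tot <- list(TP = 0L, FP = 0L, FN = 0L)
      for (i in seq_along(gold)) {
        c_i <- exact_counts(gold[[i]], pred[[i]])
        tot$TP <- tot$TP + c_i$TP; tot$FP <- tot$FP + c_i$FP
        tot$FN <- tot$FN + c_i$FN
      }
      v <- prf(tot)
      rep_ <- list(mode = "exact", precision = v[["precision"]],
                   recall = v[["recall"]], f1 = v[["f1"]], counts = tot)
    }
  } else {
    pr <- t(vapply(seq_along(gold), function(i)
      partial_sentence(gold[[i]], pred[[i]]), numeric(2)))
    both_empty <- is.na(pr[, 1]) & is.na(pr[, 2])
    if (empty_sentence == "perfect") pr[both_empty, ] <- 1
    # remaining NAs are one-sided 0/0 cases: excluded from that average
    p <- mean(pr[, 1], na.rm = TRUE); r <- mean(pr[, 2], na.rm = TRUE)
    if (is.nan(p)) p <- 0
    if (is.nan(r)) r <- 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    rep_ <- list(mode = "partial", precision = p, recall = r, f1 = f,
                 per_sentence = pr)
  }
  structure(rep_, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s matching: P = %.4f  R = %.4f  F1 = %.4f\n",
              x$mode, x$precision, x$recall, x$f1))
  invisible(x)
}
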