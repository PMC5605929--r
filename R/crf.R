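# Linear-chain conditional random field over tag sequences.
#
# The unnormalized log-score of a tag path y_1..y_n is
#
#   start[y_1] + sum_t unary[t, y_t] + sum_{t>=2} trans[y_{t-1}, y_t] + stop[y_n]
#
# i.e. the log of the product of per-position exponential potentials, with
# transition scores oriented row = from-tag, column = to-tag. The start and
# stop vectors play the role of transitions from a virtual BOS tag and to a
# virtual EOS tag; with zero vectors they reduce to the plain chain score.
# All computation is in log space with log-sum-exp stabilization; nothing is
# ever exponentiated before normalization.

#' Construct a CRF score lattice
#'
#' Holds the per-token unary tag scores emitted by the encoder network plus
#' the tag-transition matrix (and optional start/stop scores).
#'
#' @param unary n x |Y| matrix of per-position tag scores.
#' @param transitions |Y| x |Y| matrix, row = from-tag, column = to-tag;
#'   defaults to zeros.
#' @param start,stop length-|Y| score vectors for the virtual
#'   beginning-of-sentence and end-of-sentence transitions; default zeros.
#' @return object of class \code{score_lattice}.
#' @export
score_lattice <- function(unary, transitions = NULL, start = NULL, stop = NULL) {
  unary <- as.matrix(unary)
  if (nrow(unary) < 1) stop("lattice needs n >= 1 positions")
  k <- ncol(unary)
  if (is.null(transitions)) transitions <- matrix(0, k, k)
  if (is.null(start)) start <- numeric(k)
  if (is.null(stop)) stop <- numeric(k)
  transitions <- as.matrix(transitions)
  stopifnot(nrow(transitions) == k, ncol(transitions) == k,
            length(start) == k, length(stop) == k)
  if (!all(is.finite(unary)))
    stop("unary scores must be finite")
  structure(list(unary = unary, transitions = transitions,
                 start = as.numeric(start), stop = as.numeric(stop)),
            class = "score_lattice")
}

check_path <- function(lattice, path) {
  n <- nrow(lattice$unary); k <- ncol(lattice$unary)
  if (length(path) != n)
    stop("path length ", length(path), " != lattice length ", n)
  if (any(path < 1L | path > k)) stop("path contains tag indices outside 1..", k)
  as.integer(path)
}

#' Unnormalized log-score of a tag path
#'
#' The log-numerator of the CRF conditional probability: the sum of the
#' path's unary scores, adjacent-tag transition scores, and the start/stop
#' terms.
#'
#' @param lattice a [score_lattice()].
#' @param path integer vector of 1-based tag indices, one per position.
#' @return scalar log-score.
#' @export
crf_sequence_score <- function(lattice, path) {
  path <- check_path(lattice, path)
  n <- length(path)
  s <- lattice$start[path[1]] + lattice$stop[path[n]] +
    sum(lattice$unary[cbind(seq_len(n), path)])
  if (n > 1)
    s <- s + sum(lattice$transitions[cbind(path[-n], path[-1])])
  s
}

#' Log-partition function of the lattice
#'
#' Computes \code{log Z}, the log of the sum over all |Y|^n tag paths of the
#' exponentiated path score, by the forward recursion in O(n |Y|^2).
#'
#' @param lattice a [score_lattice()].
#' @return scalar \code{log Z}.
#' @export
crf_log_partition <- function(lattice) {
  u <- lattice$unary; tr <- lattice$transitions
  n <- nrow(u); k <- ncol(u)
  alpha <- lattice$start + u[1, ]
  if (n > 1) for (t in 2:n) {
    # alpha_new[y] = logsumexp_y'(alpha[y'] + tr[y', y]) + u[t, y]
    alpha <- apply(alpha + tr, 2L, logsumexp) + u[t, ]
  }
  logsumexp(alpha + lattice$stop)
}

#' Negative log-likelihood of a gold path
#'
#' \code{nll = log Z - sequence_score(gold)}; always non-negative since the
#' gold path's probability is at most 1.
#'
#' @param lattice a [score_lattice()].
#' @param gold integer tag path.
#' @return scalar NLL.
#' @export
crf_nll <- function(lattice, gold) {
  crf_log_partition(lattice) - crf_sequence_score(lattice, gold)
}

#' NLL and its exact gradient via forward-backward
#'
#' Returns the negative log-likelihood of the gold path together with its
#' analytic gradient with respect to every lattice entry: the gradient of
#' \code{log Z} is the vector of posterior marginals, so the NLL gradient is
#' marginal minus gold indicator (unary, start, stop) and expected minus
#' observed transition counts (transitions).
#'
#' @param lattice a [score_lattice()].
#' @param gold integer tag path.
#' @return list with \code{nll} and gradients \code{unary},
#'   \code{transitions}, \code{start}, \code{stop}.
#' @export
crf_nll_grad <- function(lattice, gold) {
  gold <- check_path(lattice, gold)
  u <- lattice$unary
  b <- crf_batch_nll_grad(array(u, c(1L, nrow(u), ncol(u))),
                          lengths = nrow(u),
                          transitions = lattice$transitions,
                          start = lattice$start, stop = lattice$stop,
                          gold = matrix(gold, nrow = 1L))
  list(nll = b$nll,
       unary = matrix(b$unary[1, , ], nrow(u), ncol(u)),
       transitions = b$transitions, start = b$start, stop = b$stop)
}

#' Viterbi decoding
#'
#' Returns a highest-scoring tag path and its score in O(n |Y|^2). Ties are
#' broken toward the lowest tag index, deterministically, both in the
#' per-position maxima and in the final position.
#'
#' @param lattice a [score_lattice()].
#' @return list with \code{path} (integer vector) and \code{score}.
#' @export
crf_viterbi <- function(lattice) {
  u <- lattice$unary; tr <- lattice$transitions
  n <- nrow(u); k <- ncol(u)
  delta <- lattice$start + u[1, ]
  back <- matrix(0L, n, k)
  if (n > 1) for (t in 2:n) {
    cand <- delta + tr                   # cand[y', y]
    arg <- apply(cand, 2L, which.max)    # first max = lowest index
    delta <- cand[cbind(arg, seq_len(k))] + u[t, ]
    back[t, ] <- arg
  }
  fin <- delta + lattice$stop
  last <- which.max(fin)
  path <- integer(n); path[n] <- last
  if (n > 1) for (t in n:2) path[t - 1L] <- back[t, path[t]]
  list(path = path, score = fin[last])
}

#' Forbidden transition set enforcing the BIO grammar
#'
#' For a tag inventory containing \code{O}, \code{B-X}, \code{I-X} tags,
#' returns the transition pairs that can never occur in a valid BIO
#' sequence: anything into \code{I-X} except from \code{B-X} or \code{I-X},
#' and \code{I-X} at sentence start.
#'
#' @param tagset character vector of tags.
#' @return list with \code{pairs} (2-column matrix of from/to tag indices)
#'   and \code{start} (tag indices forbidden at the first position), the
#'   format [crf_constrained_viterbi()] expects.
#' @export
bio_forbidden <- function(tagset) {
  pairs <- NULL
  start_bad <- integer()
  for (j in seq_along(tagset)) {
    tg <- tagset[j]
    if (substr(tg, 1, 1) != "I") next
    lab <- substr(tg, 3, nchar(tg))
    ok_prev <- tagset %in% c(paste0("B-", lab), paste0("I-", lab))
    for (i in which(!ok_prev)) pairs <- rbind(pairs, c(i, j))
    start_bad <- c(start_bad, j)
  }
  list(pairs = pairs, start = start_bad)
}

#' Viterbi decoding under forbidden transitions
#'
#' Identical to [crf_viterbi()] but restricted to paths avoiding a set of
#' forbidden transitions (and, optionally, forbidden first-position tags),
#' implemented by setting those scores to -Inf. With the [bio_forbidden()]
#' constraint set the output is always a valid BIO sequence.
#'
#' @param lattice a [score_lattice()].
#' @param forbidden list with elements \code{pairs} (2-column from/to index
#'   matrix, may be NULL) and \code{start} (integer vector, may be empty).
#' @return list with \code{path} and \code{score}.
#' @export
crf_constrained_viterbi <- function(lattice, forbidden = list(pairs = NULL,
                                                              start = integer())) {
  tr <- lattice$transitions
  if (!is.null(forbidden$pairs) && nrow(forbidden$pairs) > 0)
    tr[forbidden$pairs] <- -Inf
  start <- lattice$start
  if (length(forbidden$start %||% integer()) > 0)
    start[forbidden$start] <- -Inf
  res <- crf_viterbi(score_lattice(lattice$unary, tr, start, lattice$stop))
  if (!is.finite(res$score)) stop("no feasible path under the constraints")
  res
}

# ---- batched training objective --------------------------------------------

#' Batched CRF NLL and gradient over padded sequences
#'
#' Training-time objective: given a padded batch of unary score sequences,
#' computes the summed negative log-likelihood of the gold paths and its
#' gradient with respect to the unary scores, the transition matrix, and the
#' start/stop vectors. Padded positions (beyond each sequence's length)
#' contribute nothing to the loss or any gradient.
#'
#' @param unary array \code{[B, T, |Y|]} of per-position tag scores.
#' @param lengths integer vector of true sequence lengths (all \code{>= 1}).
#' @param transitions |Y| x |Y| transition matrix.
#' @param start,stop length-|Y| score vectors.
#' @param gold \code{B x T} integer matrix of gold tag indices (entries past
#'   a sequence's length are ignored).
#' @return list with \code{nll} (summed over the batch), \code{unary}
#'   (\code{[B, T, |Y|]} gradient), \code{transitions}, \code{start},
#'   \code{stop}.
#' @export
crf_batch_nll_grad <- function(unary, lengths, transitions, start, stop, gold) {
  dims <- dim(unary)
  B <- dims[1]; Tm <- dims[2]; k <- dims[3]
  stopifnot(length(lengths) == B, all(lengths >= 1), all(lengths <= Tm))
  tr <- transitions
  # forward pass, storing alpha at every position
  alphas <- vector("list", Tm)
  alpha <- matrix(start, B, k, byrow = TRUE) + unary[, 1, , drop = TRUE]
  if (B == 1) alpha <- matrix(alpha, 1, k)
  alphas[[1]] <- alpha
  if (Tm > 1) for (t in 2:Tm) {
    new <- matrix(0, B, k)
    for (y in seq_len(k))
      new[, y] <- row_logsumexp(alpha + matrix(tr[, y], B, k, byrow = TRUE))
    new <- new + matrix(unary[, t, ], B, k)
    act <- lengths >= t
    alpha[act, ] <- new[act, , drop = FALSE]
    alphas[[t]] <- alpha
  }
  logZ <- row_logsumexp(alpha + matrix(stop, B, k, byrow = TRUE))

  # gold path scores
  gs <- numeric(B)
  for (b in seq_len(B)) {
    n <- lengths[b]; p <- gold[b, seq_len(n)]
    um <- matrix(unary[b, seq_len(n), ], n, k)
    gs[b] <- start[p[1]] + stop[p[n]] + sum(um[cbind(seq_len(n), p)])
    if (n > 1) gs[b] <- gs[b] + sum(tr[cbind(p[-n], p[-1])])
  }
  nll <- sum(logZ - gs)

  # backward pass with marginal accumulation
  d_unary <- array(0, dims)
  d_tr <- matrix(0, k, k)
  d_start <- numeric(k); d_stop <- numeric(k)
  beta <- matrix(-Inf, B, k)
  for (t in Tm:1) {
    ended <- lengths == t
    if (any(ended)) beta[ended, ] <- matrix(stop, sum(ended), k, byrow = TRUE)
    act <- lengths >= t
    if (any(act)) {
      marg <- exp(alphas[[t]] + beta - logZ)      # B x k posterior marginals
      marg[!act, ] <- 0
      m <- marg
      for (b in which(act)) m[b, gold[b, t]] <- m[b, gold[b, t]] - 1
      d_unary[, t, ] <- m
      if (t == 1) d_start <- d_start + colSums(m)
      for (b in which(ended)) {
        d_stop <- d_stop + marg[b, ]
        d_stop[gold[b, t]] <- d_stop[gold[b, t]] - 1
      }
      if (t > 1) {
        # pairwise marginals between t-1 and t for sequences still active
        act2 <- lengths >= t
        a_prev <- alphas[[t - 1]]
        for (yp in seq_len(k)) for (y in seq_len(k)) {
          v <- exp(a_prev[, yp] + tr[yp, y] + unary[, t, y] + beta[, y] - logZ)
          v[!act2] <- 0
          d_tr[yp, y] <- d_tr[yp, y] + sum(v)
        }
        for (b in which(act2))
          d_tr[gold[b, t - 1], gold[b, t]] <-
            d_tr[gold[b, t - 1], gold[b, t]] - 1
        # beta_{t-1}[y'] = logsumexp_y(tr[y', y] + unary[t, y] + beta_t[y])
        nb <- matrix(0, B, k)
        inner <- matrix(unary[, t, ], B, k) + beta
        for (yp in seq_len(k))
          nb[, yp] <- row_logsumexp(inner + matrix(tr[yp, ], B, k, byrow = TRUE))
        keep <- lengths >= t
        beta[keep, ] <- nb[keep, , drop = FALSE]
      } else if (t == 1) {
        # start gradient handled above via m at t = 1
      }
    }
  }
  list(nll = nll, unary = d_unary, transitions = d_tr,
       start = d_start, stop = d_stop, logZ = logZ)
}
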