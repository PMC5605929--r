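# Neural network building blocks with hand-derived backpropagation, written
# in base R matrix code (BLAS-backed). Arrays are laid out [batch, time,
# feature]; a matrix view of rows for time t is rows ((t-1)*B + 1):(t*B) of
# matrix(x, B*T, D).

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

time_slice <- function(x_mat, t, B) x_mat[((t - 1L) * B + 1L):(t * B), , drop = FALSE]

# ---- character-level CNN ----------------------------------------------------

#' Character-CNN configuration
#'
#' @param char_vocabulary named integer index of characters (must contain
#'   the fallback entry \code{"<unk>"}).
#' @param char_dim character embedding dimension.
#' @param filter_widths convolution window widths (in characters).
#' @param filters_per_width number of filters per width; the word feature
#'   vector has length \code{length(filter_widths) * filters_per_width}.
#' @param max_word_length words longer than this are truncated.
#' @return list of class \code{char_cnn_config}.
#' @export
char_cnn_config <- function(char_vocabulary, char_dim = 25L,
                            filter_widths = c(2L, 3L, 4L),
                            filters_per_width = 25L,
                            max_word_length = 20L) {
  stopifnot(char_dim >= 1, all(filter_widths >= 1), filters_per_width >= 1,
            "<unk>" %in% names(char_vocabulary))
  structure(list(char_vocabulary = char_vocabulary, char_dim = char_dim,
                 filter_widths = as.integer(filter_widths),
                 filters_per_width = as.integer(filters_per_width),
                 max_word_length = as.integer(max_word_length)),
            class = "char_cnn_config")
}

char_cnn_init <- function(config) {
  p <- list(C = glorot(length(config$char_vocabulary), config$char_dim))
  for (w in config$filter_widths) {
    p[[sprintf("convW_w%d", w)]] <- glorot(w * config$char_dim,
                                           config$filters_per_width)
    p[[sprintf("convb_w%d", w)]] <- numeric(config$filters_per_width)
  }
  p
}

word_char_ids <- function(word, config) {
  ch <- strsplit(word, "", fixed = FALSE)[[1]]
  if (length(ch) > config$max_word_length)
    ch <- ch[seq_len(config$max_word_length)]
  idx <- config$char_vocabulary[ch]
  idx[is.na(idx)] <- config$char_vocabulary[["<unk>"]]
  as.integer(idx)
}

#' Character-CNN word features
#'
#' Embeds the word's characters, applies one-dimensional convolutions of
#' each configured width, max-pools each filter over positions, and
#' concatenates the pooled responses. Words shorter than the widest filter
#' are zero-padded on the right; words longer than \code{max_word_length}
#' are truncated.
#'
#' @param word a non-empty string.
#' @param config a [char_cnn_config()].
#' @param params parameter list holding \code{C} (character embeddings) and
#'   \code{convW_w*}/\code{convb_w*} filter banks.
#' @param cache return pooling indices for backpropagation.
#' @return numeric feature vector (with a \code{cache} attribute when
#'   requested).
#' @export
char_features <- function(word, config, params, cache = FALSE) {
  stopifnot(nzchar(word))
  ids <- word_char_ids(word, config)
  dc <- config$char_dim
  Lp <- max(length(ids), max(config$filter_widths))
  E <- matrix(0, Lp, dc)
  E[seq_along(ids), ] <- params$C[ids, , drop = FALSE]
  out <- numeric(0)
  caches <- list()
  for (w in config$filter_widths) {
    nw <- Lp - w + 1L
    X <- matrix(0, nw, w * dc)
    for (j in seq_len(w))
      X[, ((j - 1L) * dc + 1L):(j * dc)] <- E[j:(j + nw - 1L), , drop = FALSE]
    H <- X %*% params[[sprintf("convW_w%d", w)]]
    H <- sweep(H, 2L, params[[sprintf("convb_w%d", w)]], "+")
    arg <- max.col(t(H), ties.method = "first")   # argmax row per filter
    pool <- H[cbind(arg, seq_len(ncol(H)))]
    out <- c(out, pool)
    if (cache) caches[[as.character(w)]] <- list(X = X, arg = arg)
  }
  if (cache) attr(out, "cache") <- list(ids = ids, Lp = Lp, per_width = caches)
  out
}

# Backprop for one word: dpool is the gradient on the concatenated feature
# vector. Accumulates into grads (an environment-like list returned).
char_features_backward <- function(dpool, config, params, cache, grads) {
  dc <- config$char_dim
  K <- config$filters_per_width
  off <- 0L
  dE <- matrix(0, cache$Lp, dc)
  for (w in config$filter_widths) {
    cw <- cache$per_width[[as.character(w)]]
    dp <- dpool[(off + 1L):(off + K)]
    off <- off + K
    nm_w <- sprintf("convW_w%d", w); nm_b <- sprintf("convb_w%d", w)
    dH <- matrix(0, nrow(cw$X), K)
    dH[cbind(cw$arg, seq_len(K))] <- dp
    grads[[nm_w]] <- grads[[nm_w]] + crossprod(cw$X, dH)
    grads[[nm_b]] <- grads[[nm_b]] + colSums(dH)
    dX <- dH %*% t(params[[nm_w]])
    nw <- nrow(cw$X)
    for (j in seq_len(w))
      dE[j:(j + nw - 1L), ] <- dE[j:(j + nw - 1L), ] +
        dX[, ((j - 1L) * dc + 1L):(j * dc), drop = FALSE]
  }
  ids <- cache$ids
  for (i in seq_along(ids))
    grads$C[ids[i], ] <- grads$C[ids[i], ] + dE[i, ]
  grads
}

# ---- recurrent cells --------------------------------------------------------

rnn_init <- function(cell, d_in, h) {
  ng <- if (cell == "lstm") 4L else 3L
  b <- numeric(ng * h)
  if (cell == "lstm") b[(h + 1L):(2L * h)] <- 1   # forget-gate bias
  list(W = glorot(d_in, ng * h), U = glorot(h, ng * h), b = b)
}

# One direction of one recurrent layer over a padded batch.
# x: [B, T, D] array; mask: B x T; returns H [B, T, h] plus caches.
rnn_forward <- function(x, mask, W, U, b, cell, reverse = FALSE) {
  dims <- dim(x); B <- dims[1]; Tm <- dims[2]; D <- dims[3]
  h <- nrow(U)
  xp <- matrix(x, B * Tm, D) %*% W
  xp <- sweep(xp, 2L, b, "+")
  ord <- if (reverse) Tm:1 else 1:Tm
  H <- array(0, c(B, Tm, h))
  hs <- matrix(0, B, h)
  cs <- matrix(0, B, h)           # LSTM cell state
  caches <- vector("list", Tm)
  i1 <- 1L:h; i2 <- (h + 1L):(2L * h); i3 <- (2L * h + 1L):(3L * h)
  if (cell == "lstm") i4 <- (3L * h + 1L):(4L * h)
  for (t in ord) {
    a <- time_slice(xp, t, B)
    m <- mask[, t]
    if (cell == "gru") {
      z <- sigmoid(a[, i1, drop = FALSE] + hs %*% U[, i1])
      r <- sigmoid(a[, i2, drop = FALSE] + hs %*% U[, i2])
      cc <- tanh(a[, i3, drop = FALSE] + (r * hs) %*% U[, i3])
      hn <- z * hs + (1 - z) * cc
      caches[[t]] <- list(h_prev = hs, z = z, r = r, c = cc)
      hs <- m * hn + (1 - m) * hs
    } else {
      ig <- sigmoid(a[, i1, drop = FALSE] + hs %*% U[, i1])
      fg <- sigmoid(a[, i2, drop = FALSE] + hs %*% U[, i2])
      og <- sigmoid(a[, i3, drop = FALSE] + hs %*% U[, i3])
      gg <- tanh(a[, i4, drop = FALSE] + hs %*% U[, i4])
      cn <- fg * cs + ig * gg
      th <- tanh(cn)
      hn <- og * th
      caches[[t]] <- list(h_prev = hs, c_prev = cs, i = ig, f = fg, o = og,
                          g = gg, th = th)
      cs <- m * cn + (1 - m) * cs
      hs <- m * hn + (1 - m) * hs
    }
    H[, t, ] <- hs
  }
  list(H = H, caches = caches, xp_dim = D, ord = ord)
}

# Backprop through one direction. dH: [B, T, h] external gradient on the
# outputs. Returns dx [B, T, D], dW, dU, db.
rnn_backward <- function(x, mask, W, U, b, cell, reverse, fwd, dH) {
  dims <- dim(x); B <- dims[1]; Tm <- dims[2]; D <- dims[3]
  h <- nrow(U)
  ord <- fwd$ord
  i1 <- 1L:h; i2 <- (h + 1L):(2L * h); i3 <- (2L * h + 1L):(3L * h)
  if (cell == "lstm") i4 <- (3L * h + 1L):(4L * h)
  ng <- if (cell == "lstm") 4L else 3L
  dW <- matrix(0, D, ng * h); dU <- matrix(0, h, ng * h); db <- numeric(ng * h)
  dx <- array(0, c(B, Tm, D))
  dh_carry <- matrix(0, B, h)
  dc_carry <- matrix(0, B, h)
  xmat <- matrix(x, B * Tm, D)
  for (t in rev(ord)) {
    cch <- fwd$caches[[t]]
    m <- mask[, t]
    dh_tot <- dH[, t, ] + dh_carry
    if (is.null(dim(dh_tot))) dh_tot <- matrix(dh_tot, B, h)
    dh_new <- dh_tot * m
    dh_prev <- dh_tot * (1 - m)
    if (cell == "gru") {
      z <- cch$z; r <- cch$r; cc <- cch$c; hp <- cch$h_prev
      dz <- dh_new * (hp - cc)
      dc <- dh_new * (1 - z)
      dh_prev <- dh_prev + dh_new * z
      dc_pre <- dc * (1 - cc * cc)
      d_rh <- dc_pre %*% t(U[, i3])
      dr <- d_rh * hp
      dh_prev <- dh_prev + d_rh * r
      dz_pre <- dz * z * (1 - z)
      dr_pre <- dr * r * (1 - r)
      dU[, i1] <- dU[, i1] + crossprod(hp, dz_pre)
      dU[, i2] <- dU[, i2] + crossprod(hp, dr_pre)
      dU[, i3] <- dU[, i3] + crossprod(r * hp, dc_pre)
      dh_prev <- dh_prev + dz_pre %*% t(U[, i1]) + dr_pre %*% t(U[, i2])
      dA <- cbind(dz_pre, dr_pre, dc_pre)
    } else {
      ig <- cch$i; fg <- cch$f; og <- cch$o; gg <- cch$g; th <- cch$th
      hp <- cch$h_prev; cp <- cch$c_prev
      dc_new <- dc_carry * m
      dc_prev <- dc_carry * (1 - m)
      do_ <- dh_new * th
      dc_new <- dc_new + dh_new * og * (1 - th * th)
      df <- dc_new * cp
      di <- dc_new * gg
      dg <- dc_new * ig
      dc_prev <- dc_prev + dc_new * fg
      di_pre <- di * ig * (1 - ig)
      df_pre <- df * fg * (1 - fg)
      do_pre <- do_ * og * (1 - og)
      dg_pre <- dg * (1 - gg * gg)
      dA <- cbind(di_pre, df_pre, do_pre, dg_pre)
      dU <- dU + crossprod(hp, dA)
      dh_prev <- dh_prev + dA %*% t(U)
      dc_carry <- dc_prev
    }
    db <- db + colSums(dA)
    xt <- time_slice(xmat, t, B)
    dW <- dW + crossprod(xt, dA)
    dx[, t, ] <- dA %*% t(W)
    dh_carry <- dh_prev
  }
  list(dx = dx, dW = dW, dU = dU, db = db)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# Default Adam hyperparameters (lr 0.001, beta1 0.9, beta2 0.999, eps 1e-8).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
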