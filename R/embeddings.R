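# Word embedding I/O in word2vec text format and OOV initialization.

#' Read a word2vec-format text embedding file
#'
#' Format: a header line "count dim", then one "word v1 ... vd" line per
#' word.
#'
#' @param path file path.
#' @return list with \code{words} (character) and \code{vectors}
#'   (|V| x d matrix, rows named by word).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty embedding file: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop("malformed word2vec header: ", lines[1])
  d <- hdr[2]
  body <- lines[-1]
  body <- body[nzchar(body)]
  words <- character(length(body))
  vecs <- matrix(0, length(body), d)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], " ", fixed = TRUE)[[1]]
    if (length(parts) != d + 1)
      stop("embedding line ", i + 1, " has ", length(parts) - 1,
           " values, expected ", d)
    words[i] <- parts[1]
    v <- as.numeric(parts[-1])
    if (anyNA(v)) stop("non-numeric embedding value at line ", i + 1)
    vecs[i, ] <- v
  }
  rownames(vecs) <- words
  list(words = words, vectors = vecs)
}

#' Write embeddings in word2vec text format
#'
#' @param words character vector.
#' @param vectors matrix with one row per word.
#' @param path output path.
#' @export
write_word2vec <- function(words, vectors, path) {
  stopifnot(length(words) == nrow(vectors))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(words), ncol(vectors)), con, sep = "\n")
  for (i in seq_along(words))
    writeLines(paste(words[i],
                     paste(sprintf("%.8g", vectors[i, ]), collapse = " ")),
               con, sep = "\n")
  invisible(path)
}

#' Build an embedding table for a vocabulary
#'
#' In-vocabulary words receive their file vectors. Out-of-vocabulary words
#' are initialized with i.i.d. uniform samples from the range
#' \code{[min, max]} of all loaded embedding weights, the standard recipe
#' for unseen words; sampling is deterministic given \code{seed}.
#'
#' @param path word2vec text file.
#' @param vocabulary character vector of words the model needs.
#' @param seed integer seed for the OOV draws.
#' @return list of class \code{embedding_table}: \code{vocabulary} (named
#'   index), \code{vectors} (|vocabulary| x d, rows in vocabulary order),
#'   \code{oov} (logical per word), \code{oov_range} \code{c(low, high)}.
#' @export
load_embeddings <- function(path, vocabulary, seed = 1L) {
  emb <- read_word2vec(path)
  d <- ncol(emb$vectors)
  lo <- min(emb$vectors); hi <- max(emb$vectors)
  if (!is.finite(lo)) { lo <- -0.25; hi <- 0.25 }   # empty-file fallback
  vocabulary <- as.character(vocabulary)
  vec <- matrix(0, length(vocabulary), d)
  hit <- vocabulary %in% emb$words
  if (any(hit)) vec[hit, ] <- emb$vectors[vocabulary[hit], , drop = FALSE]
  if (any(!hit))
    vec[!hit, ] <- with_seed(seed,
      matrix(runif(sum(!hit) * d, lo, hi), sum(!hit), d))
  rownames(vec) <- vocabulary
  structure(list(vocabulary = stats::setNames(seq_along(vocabulary), vocabulary),
                 vectors = vec, oov = !hit, oov_range = c(lo, hi)),
            class = "embedding_table")
}
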