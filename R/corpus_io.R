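# Corpus I/O: brat standoff and CoNLL readers/writers, tokenization,
# overlap resolution, and the span <-> BIO codec.
#
# All character offsets are 0-based half-open [start, end), the brat
# convention; a span's surface text is substr(text, start + 1, end) in
# R's 1-based coordinates.

# ---- span containers --------------------------------------------------------

#' Construct a span table
#'
#' Spans are stored as a plain data.frame with columns \code{start},
#' \code{end} (0-based half-open character offsets), \code{label} and
#' \code{text}. This is the unit of gold and predicted annotation.
#'
#' @param start,end integer offset vectors (half-open).
#' @param label entity label, recycled; always \code{"ADR"} in this package's
#'   core task.
#' @param text surface strings (optional, may be \code{NA}).
#' @return a \code{data.frame} of spans, sorted as given.
#' @export
entity_spans <- function(start = integer(), end = integer(),
                         label = character(), text = NA_character_) {
  n <- length(start)
  if (length(end) != n) stop("start and end must have equal length")
  if (n > 0 && any(start >= end)) stop("every span needs start < end")
  if (n > 0 && length(label) == 0) label <- "ADR"
  data.frame(start = as.integer(start), end = as.integer(end),
             label = rep_len(as.character(label), n),
             text = rep_len(as.character(text), n),
             stringsAsFactors = FALSE)
}

empty_spans <- function() entity_spans()

#' Construct a document
#'
#' A document is one review/forum post: raw text plus its annotated entity
#' spans. Span offsets are validated against the text.
#'
#' @param doc_id document identifier.
#' @param text raw review text.
#' @param spans span table as from [entity_spans()].
#' @return an object of class \code{adr_document}.
#' @export
adr_document <- function(doc_id, text, spans = empty_spans()) {
  stopifnot(is.character(doc_id), is.character(text))
  if (nrow(spans) > 0) {
    if (any(spans$start < 0) || any(spans$end > nchar(text)))
      stop("span offsets outside [0, nchar(text)] in document ", doc_id)
  }
  structure(list(doc_id = doc_id, text = text, spans = spans),
            class = "adr_document")
}

#' @export
print.adr_document <- function(x, ...) {
  cat(sprintf("<adr_document %s: %d chars, %d spans>\n",
              x$doc_id, nchar(x$text), nrow(x$spans)))
  invisible(x)
}

span_text <- function(text, start, end) {
  if (length(start) == 0) return(character())
  substring(text, start + 1L, end)
}

# ---- tokenization -----------------------------------------------------------

#' Tokenize text with character offsets
#'
#' Rule-based tokenizer: split on whitespace, then peel leading and trailing
#' punctuation characters off each chunk as separate tokens. Internal
#' punctuation (hyphens, apostrophes) stays inside the token. Offsets index
#' into the original text, so downstream evaluation is offset-true and the
#' original text is always recoverable.
#'
#' @param text a single string.
#' @return data.frame with columns \code{surface}, \code{start}, \code{end}.
#' @export
tokenize_text <- function(text) {
  stopifnot(length(text) == 1L)
  out_surface <- character(); out_start <- integer(); out_end <- integer()
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] != -1) {
    for (i in seq_along(m)) {
      s0 <- as.integer(m[i]) - 1L                 # 0-based chunk start
      chunk <- substr(text, m[i], m[i] + attr(m, "match.length")[i] - 1L)
      # peel leading punctuation
      lead <- regmatches(chunk, regexpr("^[[:punct:]]+", chunk))
      core <- chunk
      off <- s0
      if (length(lead) == 1L && nchar(lead) < nchar(chunk)) {
        for (j in seq_len(nchar(lead))) {
          out_surface <- c(out_surface, substr(lead, j, j))
          out_start <- c(out_start, off); out_end <- c(out_end, off + 1L)
          off <- off + 1L
        }
        core <- substr(chunk, nchar(lead) + 1L, nchar(chunk))
      }
      trail <- regmatches(core, regexpr("[[:punct:]]+$", core))
      tail_n <- if (length(trail) == 1L && nchar(trail) < nchar(core))
        nchar(trail) else 0L
      core_main <- substr(core, 1L, nchar(core) - tail_n)
      if (nchar(core_main) > 0) {
        out_surface <- c(out_surface, core_main)
        out_start <- c(out_start, off)
        out_end <- c(out_end, off + nchar(core_main))
      }
      if (tail_n > 0) {
        toff <- off + nchar(core_main)
        for (j in seq_len(tail_n)) {
          out_surface <- c(out_surface,
                           substr(core, nchar(core) - tail_n + j,
                                  nchar(core) - tail_n + j))
          out_start <- c(out_start, toff); out_end <- c(out_end, toff + 1L)
          toff <- toff + 1L
        }
      }
    }
  }
  data.frame(surface = out_surface, start = out_start, end = out_end,
             stringsAsFactors = FALSE)
}

# Sentence boundaries: after runs of .!? followed by whitespace/end, and at
# newlines. Returns 0-based half-open [start, end) ranges covering the text.
sentence_ranges <- function(text) {
  n <- nchar(text)
  if (n == 0) return(data.frame(start = integer(), end = integer()))
  m <- gregexpr("[.!?]+(?=\\s|$)|\n", text, perl = TRUE)[[1]]
  cuts <- integer()
  if (m[1] != -1)
    cuts <- as.integer(m) + attr(m, "match.length") - 1L  # 0-based, exclusive
  cuts <- sort(unique(c(cuts, n)))
  starts <- c(0L, cuts[-length(cuts)])
  data.frame(start = starts, end = cuts)
}

#' Split a document into sentences
#'
#' Sentences are the tagging unit. Each sentence carries its document id, its
#' index within the document, and a token table whose offsets are absolute
#' (document-level), so spans can be projected onto tokens directly.
#' Token-free ranges (e.g. runs of whitespace) are dropped.
#'
#' @param doc an [adr_document()].
#' @return list of sentence objects (class \code{adr_sentence}).
#' @export
doc_sentences <- function(doc) {
  toks <- tokenize_text(doc$text)
  rng <- sentence_ranges(doc$text)
  out <- list()
  idx <- 0L
  for (i in seq_len(nrow(rng))) {
    sel <- toks$start >= rng$start[i] & toks$start < rng$end[i]
    if (!any(sel)) next
    idx <- idx + 1L
    out[[idx]] <- structure(
      list(doc_id = doc$doc_id, index = idx, tokens = toks[sel, , drop = FALSE]),
      class = "adr_sentence")
  }
  out
}

# ---- brat standoff ----------------------------------------------------------

#' Parse a brat standoff annotation pair
#'
#' Reads a document from its raw text and the content of a brat \code{.ann}
#' file. Only textbound (\code{T...}) lines are interpreted; other brat line
#' types (attributes, relations, notes) are ignored. Discontinuous spans
#' (\code{start end;start end}) are collapsed to their minimal covering
#' interval and flagged in a \code{discontinuous} column so that
#' [resolve_overlaps()] can combine them downstream. If a record's quoted
#' text disagrees with the document substring at its offsets, a warning is
#' raised and the offsets are kept as authoritative.
#'
#' @param text document text (contents of the \code{.txt} file).
#' @param ann contents of the \code{.ann} file.
#' @param doc_id document identifier.
#' @param keep_labels if non-NULL, retain only these entity labels
#'   (e.g. \code{"ADR"}).
#' @return an [adr_document()]; its span table gains a \code{discontinuous}
#'   logical column.
#' @export
read_brat <- function(text, ann, doc_id = "doc", keep_labels = NULL) {
  lines <- if (nzchar(ann)) strsplit(ann, "\n", fixed = TRUE)[[1]] else character()
  starts <- integer(); ends <- integer(); labels <- character()
  texts <- character(); disc <- logical()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line) || substr(line, 1, 1) != "T") next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop("malformed brat annotation at line ", i, ": ", line)
    head <- parts[2]
    quoted <- if (length(parts) >= 3) parts[3] else ""
    hp <- strsplit(head, " ", fixed = TRUE)[[1]]
    if (length(hp) < 3)
      stop("malformed brat annotation at line ", i, ": ", line)
    label <- hp[1]
    frag_str <- paste(hp[-1], collapse = " ")
    frags <- strsplit(frag_str, ";", fixed = TRUE)[[1]]
    nums <- lapply(frags, function(f) {
      v <- suppressWarnings(as.integer(strsplit(trimws(f), " ")[[1]]))
      if (length(v) != 2 || anyNA(v))
        stop("malformed brat offsets at line ", i, ": ", line)
      v
    })
    s <- min(vapply(nums, `[`, integer(1), 1L))
    e <- max(vapply(nums, `[`, integer(1), 2L))
    if (s >= e) stop("malformed brat offsets at line ", i, ": ", line)
    actual <- span_text(text, s, e)
    if (length(nums) == 1L && nzchar(quoted) && !identical(quoted, actual))
      warning(sprintf(
        "document %s line %d: annotated text %s != document substring %s; keeping offsets",
        doc_id, i, dQuote(quoted), dQuote(actual)))
    starts <- c(starts, s); ends <- c(ends, e); labels <- c(labels, label)
    texts <- c(texts, actual); disc <- c(disc, length(nums) > 1L)
  }
  spans <- entity_spans(starts, ends, labels, texts)
  spans$discontinuous <- disc
  if (!is.null(keep_labels)) {
    spans <- spans[spans$label %in% keep_labels, , drop = FALSE]
    rownames(spans) <- NULL
  }
  adr_document(doc_id, text, spans)
}

#' Read a brat .txt/.ann file pair from disk
#'
#' @param txt_path,ann_path paths to the text and annotation files.
#' @param ... passed to [read_brat()].
#' @return an [adr_document()].
#' @export
read_brat_pair <- function(txt_path, ann_path, ...) {
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  ann <- paste(readLines(ann_path, warn = FALSE), collapse = "\n")
  read_brat(text, ann, doc_id = sub("\\.txt$", "", basename(txt_path)), ...)
}

#' Write a document as a brat .txt/.ann pair
#'
#' @param doc an [adr_document()].
#' @param txt_path,ann_path output paths.
#' @export
write_brat_pair <- function(doc, txt_path, ann_path) {
  writeLines(doc$text, txt_path, sep = "\n")
  sp <- doc$spans
  lines <- character(nrow(sp))
  for (i in seq_len(nrow(sp)))
    lines[i] <- sprintf("T%d\t%s %d %d\t%s", i, sp$label[i], sp$start[i],
                        sp$end[i], span_text(doc$text, sp$start[i], sp$end[i]))
  writeLines(lines, ann_path)
  invisible(doc)
}

# ---- overlap resolution -----------------------------------------------------

#' Resolve overlapping entity spans
#'
#' Annotated ADR spans can overlap (including the covering intervals of
#' discontinuous annotations). Each group of transitively overlapping spans
#' is replaced by a single span covering the union interval of the group --
#' the longest continuous span containing them all. Disjoint spans pass
#' through unchanged. Overlap is strict interval intersection: spans that
#' merely touch (\code{end == start}) are not merged. The operation is
#' idempotent and its output is sorted by start.
#'
#' @param spans span table.
#' @param text optional document text used to fill the merged spans'
#'   \code{text} column.
#' @return non-overlapping span table.
#' @export
resolve_overlaps <- function(spans, text = NULL) {
  if (nrow(spans) == 0) return(empty_spans())
  o <- order(spans$start, spans$end)
  s <- spans$start[o]; e <- spans$end[o]; lab <- spans$label[o]
  rs <- s[1]; re <- e[1]; rl <- lab[1]
  out_s <- integer(); out_e <- integer(); out_l <- character()
  for (i in seq_along(s)[-1]) {
    if (s[i] < re) {          # strict overlap with current group
      re <- max(re, e[i])
    } else {
      out_s <- c(out_s, rs); out_e <- c(out_e, re); out_l <- c(out_l, rl)
      rs <- s[i]; re <- e[i]; rl <- lab[i]
    }
  }
  out_s <- c(out_s, rs); out_e <- c(out_e, re); out_l <- c(out_l, rl)
  txt <- if (is.null(text)) NA_character_ else span_text(text, out_s, out_e)
  entity_spans(out_s, out_e, out_l, txt)
}

# ---- BIO codec --------------------------------------------------------------

bio_tagset <- function(label = "ADR")
  c("O", paste0("B-", label), paste0("I-", label))

spans_overlap_token <- function(tok_start, tok_end, sp_start, sp_end)
  tok_start < sp_end & tok_end > sp_start

#' Project entity spans onto a sentence as BIO tags
#'
#' Any token whose character interval intersects a span is included in it
#' (partial overlap counts); the first such token of each span gets the
#' \code{B-} tag, the rest \code{I-}. Remaining tokens are \code{O}. Spans
#' that touch no token of the sentence are ignored.
#'
#' @param sentence an \code{adr_sentence}.
#' @param spans non-overlapping span table (run [resolve_overlaps()] first).
#' @return character vector of tags, one per token.
#' @export
spans_to_bio <- function(sentence, spans) {
  toks <- sentence$tokens
  n <- nrow(toks)
  tags <- rep("O", n)
  if (nrow(spans) == 0) return(tags)
  o <- order(spans$start)
  sp <- spans[o, , drop = FALSE]
  if (nrow(sp) > 1 && any(sp$start[-1] < sp$end[-nrow(sp)]))
    stop("spans overlap; run resolve_overlaps() before spans_to_bio()")
  for (i in seq_len(nrow(sp))) {
    hit <- which(spans_overlap_token(toks$start, toks$end, sp$start[i], sp$end[i]))
    if (length(hit) == 0) next
    tags[hit[1]] <- paste0("B-", sp$label[i])
    if (length(hit) > 1) tags[hit[-1]] <- paste0("I-", sp$label[i])
  }
  tags
}

#' Decode a BIO tag sequence into entity spans
#'
#' Maximal runs matching \code{B-X (I-X)*} become spans from the first
#' token's start to the last token's end. In \code{"repair"} mode (default),
#' an \code{I-X} that follows \code{O}, sentence start, or a different
#' label opens a new span as if it were \code{B-X} -- softmax-decoded
#' taggers routinely emit such sequences and they are still evaluated. In
#' \code{"strict"} mode invalid openings raise an error.
#'
#' @param sentence an \code{adr_sentence}.
#' @param tags character vector of BIO tags, one per token.
#' @param mode \code{"repair"} or \code{"strict"}.
#' @return span table with character offsets (and the covered surface text).
#' @export
bio_to_spans <- function(sentence, tags, mode = c("repair", "strict")) {
  mode <- match.arg(mode)
  toks <- sentence$tokens
  if (length(tags) != nrow(toks))
    stop("tag sequence length ", length(tags),
         " != token count ", nrow(toks))
  starts <- integer(); ends <- integer(); labels <- character()
  cur_label <- NULL; cur_first <- NA_integer_; cur_last <- NA_integer_
  close_run <- function() {
    if (!is.null(cur_label)) {
      starts <<- c(starts, toks$start[cur_first])
      ends <<- c(ends, toks$end[cur_last])
      labels <<- c(labels, cur_label)
    }
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") { close_run(); cur_label <- NULL; next }
    kind <- substr(tg, 1, 1)
    lab <- substr(tg, 3, nchar(tg))
    if (kind == "B" || is.null(cur_label) || lab != cur_label) {
      if (kind == "I" && mode == "strict" &&
          (is.null(cur_label) || lab != cur_label))
        stop("invalid BIO: orphan ", tg, " at token ", i)
      close_run()
      cur_label <- lab; cur_first <- i; cur_last <- i
    } else {
      cur_last <- i
    }
  }
  close_run()
  sp <- entity_spans(starts, ends, labels)
  if (nrow(sp) > 0)
    sp$text <- mapply(function(s, e) {
      sel <- toks$start >= s & toks$end <= e
      paste(toks$surface[sel], collapse = " ")
    }, sp$start, sp$end)
  sp
}

# ---- corpus split -----------------------------------------------------------

#' Split documents into training and test sets
#'
#' Document-level (never sentence-level) random split, deterministic for a
#' given seed. The partition is exhaustive and disjoint.
#'
#' @param documents list of [adr_document()]s.
#' @param train_fraction fraction of documents assigned to training
#'   (default 0.70).
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
split_corpus <- function(documents, train_fraction = 0.7, seed = 1L) {
  n <- length(documents)
  if (n < 2) stop("need at least 2 documents to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- with_seed(seed, sample.int(n))
  list(train = documents[sort(perm[seq_len(n_train)])],
       test = documents[sort(perm[-seq_len(n_train)])])
}

# ---- CoNLL format -----------------------------------------------------------

#' Write sentences and tags in CoNLL token-per-line format
#'
#' One token per line as \code{surface<TAB>tag}, a blank line after each
#' sentence (including the last). [read_conll()] inverts this bit-exactly.
#'
#' @param sentences list of \code{adr_sentence}s.
#' @param tags list of tag vectors aligned with \code{sentences}.
#' @param path output file path.
#' @export
write_conll <- function(sentences, tags, path) {
  stopifnot(length(sentences) == length(tags))
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(sentences)) {
    surf <- sentences[[i]]$tokens$surface
    tg <- tags[[i]]
    if (length(tg) != length(surf))
      stop("sentence ", i, ": tag/token length mismatch")
    writeLines(c(paste0(surf, "\t", tg), ""), con, sep = "\n")
  }
  invisible(path)
}

#' Read a CoNLL token-per-line file
#'
#' @param path input file path.
#' @return list with \code{sentences} (list of \code{adr_sentence}s with
#'   offsets synthesized by single-space joining) and \code{tags} (list of
#'   tag vectors).
#' @export
read_conll <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sentences <- list(); tags <- list()
  cur_surf <- character(); cur_tag <- character()
  flush <- function() {
    if (length(cur_surf) > 0) {
      ends <- cumsum(nchar(cur_surf) + 1L) - 1L
      starts <- c(0L, ends[-length(ends)] + 1L)
      s <- structure(list(
        doc_id = sprintf("conll_%d", length(sentences) + 1L),
        index = length(sentences) + 1L,
        tokens = data.frame(surface = cur_surf, start = starts, end = ends,
                            stringsAsFactors = FALSE)),
        class = "adr_sentence")
      sentences[[length(sentences) + 1L]] <<- s
      tags[[length(tags) + 1L]] <<- cur_tag
    }
    cur_surf <<- character(); cur_tag <<- character()
  }
  for (line in lines) {
    if (!nzchar(line)) { flush(); next }
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed CoNLL line: ", line)
    cur_surf <- c(cur_surf, parts[1]); cur_tag <- c(cur_tag, parts[2])
  }
  flush()
  list(sentences = sentences, tags = tags)
}
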