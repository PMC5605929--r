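# Group-distinct ADR term mining over reviews with demographic metadata:
# keep a term for a demographic group when it appears in more than four of
# that group's reviews and its exact normalized form never appears in a
# review carrying a different tag of the same dimension.

#' Normalize an ADR term for exact matching
#'
#' Lowercases and collapses internal whitespace; no stemming -- matching is
#' exact on the normalized string.
#'
#' @param term character vector.
#' @return normalized character vector.
#' @export
normalize_term <- function(term) {
  gsub("\\s+", " ", trimws(tolower(term)))
}

#' Mine demographic group-distinct ADR terms
#'
#' For each value of the grouping dimension (gender or age group): a
#' candidate term is one occurring in more than \code{threshold} reviews of
#' the group (each review counted once per term by default); a candidate is
#' kept only if its exact normalized form never occurs in any review with a
#' different tag. Reviews whose tag is \code{"unknown"} are dropped from
#' the grouping when \code{drop_unknown} is TRUE. Terms are ordered by
#' descending count, then lexicographically.
#'
#' @param extracted named list mapping review_id to a character vector of
#'   extracted ADR terms.
#' @param metadata data.frame with columns \code{review_id} plus the
#'   grouping column (\code{gender} or \code{age_group}).
#' @param grouping which metadata column defines the groups.
#' @param threshold minimum review count, exclusive (default 4: a term must
#'   appear in more than four reviews).
#' @param counting \code{"review"} (each review counts once per term) or
#'   \code{"occurrence"} (raw occurrence counts; the exclusivity rule still
#'   uses review-level presence).
#' @param drop_unknown ignore reviews tagged \code{"unknown"}.
#' @return named list (class \code{group_term_report}) of
#'   data.frames with columns \code{term} and \code{count}.
#' @export
distinct_terms <- function(extracted, metadata,
                           grouping = c("gender", "age_group"),
                           threshold = 4L,
                           counting = c("review", "occurrence"),
                           drop_unknown = TRUE) {
  grouping <- match.arg(grouping)
  counting <- match.arg(counting)
  if (!grouping %in% names(metadata))
    stop("metadata lacks a ", grouping, " column")
  if (anyDuplicated(metadata$review_id))
    stop("review_id values in metadata must be unique")
  ids <- names(extracted)
  missing <- setdiff(ids, metadata$review_id)
  if (length(missing) > 0)
    stop("missing metadata for review(s): ", paste(missing, collapse = ", "))
  tag <- stats::setNames(as.character(metadata[[grouping]]),
                         metadata$review_id)[ids]
  if (drop_unknown) {
    keep <- !is.na(tag) & tag != "unknown"
    extracted <- extracted[keep]; ids <- ids[keep]; tag <- tag[keep]
  }
  # long table: one row per (review, term); presence is review-level
  rows <- lapply(ids, function(id) {
    tm <- normalize_term(extracted[[id]])
    tm <- tm[nzchar(tm)]
    if (length(tm) == 0) return(NULL)
    data.frame(review_id = id, term = tm, group = tag[[id]],
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  groups <- sort(unique(tag))
  report <- stats::setNames(vector("list", length(groups)), groups)
  if (is.null(long)) {
    for (g in groups) report[[g]] <- data.frame(term = character(),
                                                count = integer())
    return(structure(report, class = "group_term_report"))
  }
  pres <- unique(long[, c("review_id", "term", "group")])
  for (g in groups) {
    cnt_src <- if (counting == "review") pres else long
    tab <- table(cnt_src$term[cnt_src$group == g])
    cand <- names(tab)[tab > threshold]
    outside <- unique(pres$term[pres$group != g])
    keep <- setdiff(cand, outside)
    cnt <- as.integer(tab[keep])
    o <- order(-cnt, keep)
    report[[g]] <- data.frame(term = keep[o], count = cnt[o],
                              stringsAsFactors = FALSE)
  }
  structure(report, class = "group_term_report")
}

#' Terms over the whole collection ("all authors" row)
#'
#' Review-level term counts over every review, thresholded but with no
#' cross-group exclusion.
#'
#' @inheritParams distinct_terms
#' @return data.frame with \code{term} and \code{count}, ordered by
#'   descending count then term.
#' @export
all_authors_terms <- function(extracted, threshold = 4L,
                              counting = c("review", "occurrence")) {
  counting <- match.arg(counting)
  ids <- names(extracted)
  rows <- lapply(ids, function(id) {
    tm <- normalize_term(extracted[[id]])
    tm <- tm[nzchar(tm)]
    if (length(tm) == 0) return(NULL)
    data.frame(review_id = id, term = tm, stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  if (is.null(long)) return(data.frame(term = character(), count = integer()))
  src <- if (counting == "review") unique(long) else long
  tab <- table(src$term)
  keep <- names(tab)[tab > threshold]
  cnt <- as.integer(tab[keep])
  o <- order(-cnt, keep)
  data.frame(term = keep[o], count = cnt[o], stringsAsFactors = FALSE)
}

#' @export
print.group_term_report <- function(x, ...) {
  for (g in names(x)) {
    cat(sprintf("%s (%d terms): %s\n", g, nrow(x[[g]]),
                paste(utils::head(x[[g]]$term, 8), collapse = ", ")))
  }
  invisible(x)
}

#' Write a group-term report as a delimited table
#'
#' One row per (group, term, count), tab-separated.
#'
#' @param report a \code{group_term_report}.
#' @param path output path.
#' @export
write_group_terms <- function(report, path) {
  rows <- do.call(rbind, lapply(names(report), function(g)
    if (nrow(report[[g]]) > 0)
      data.frame(group = g, report[[g]], stringsAsFactors = FALSE)))
  if (is.null(rows))
    rows <- data.frame(group = character(), term = character(),
                       count = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
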