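# String similarities used by the linkage scorer.  All comparisons run
# on normalized values; "not comparable" (both sides empty) is the
# scorer's business, signalled here as NA.

#' Normalized Levenshtein similarity
#'
#' `1 - L(a, b) / max(|a|, |b|)` with unit edit costs, computed through
#' [utils::adist()]. Symmetric; equals 1 exactly when the strings are
#' equal. When both sides are empty the pair carries no information and
#' `NA` is returned (the scorer drops such fields); one empty side
#' against a non-empty side scores 0. Vectorised with recycling.
#'
#' @param a,b character vectors of normalized strings.
#' @return numeric vector in `[0, 1]`, or `NA` where both are empty.
#' @export
#' @examples
#' similarity_text("FELLEGI", "FELLIGI") # 1 - 1/7
similarity_text <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  la <- nchar(a)
  lb <- nchar(b)
  out <- numeric(n)
  both_empty <- la == 0L & lb == 0L
  out[both_empty] <- NA_real_
  live <- !both_empty
  if (any(live)) {
    d <- mapply(function(x, y) utils::adist(x, y)[1L, 1L], a[live], b[live],
                USE.NAMES = FALSE)
    out[live] <- 1 - d / pmax(la[live], lb[live])
  }
  out
}

#' Similarity of multi-component names
#'
#' Splits both names on spaces and greedily assigns components one to
#' one, best pairs first, by [similarity_text()]; the score is the mean
#' over the shorter component list, so "IVAN PETER" against "IVAN" is a
#' perfect 1.0 — a dropped middle name is not an error. With one
#' component on either side this reduces to plain text similarity.
#'
#' @param a,b normalized name strings (components separated by spaces).
#' @return numeric scalar in `[0, 1]`, or `NA` when both empty.
#' @export
#' @examples
#' similarity_name("IVAN PETER", "IVAN")
#' similarity_name("ANNA MARIA", "MARIA ANNA")
similarity_name <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L) {
    return(mapply(similarity_name, a, b, USE.NAMES = FALSE))
  }
  if (!nzchar(a) && !nzchar(b)) return(NA_real_)
  if (!nzchar(a) || !nzchar(b)) return(0)
  ca <- strsplit(a, " ", fixed = TRUE)[[1]]
  cb <- strsplit(b, " ", fixed = TRUE)[[1]]
  if (length(ca) == 1L && length(cb) == 1L) return(similarity_text(a, b))
  sim <- 1 - utils::adist(ca, cb) / outer(nchar(ca), nchar(cb), pmax)
  if (length(ca) > length(cb)) sim <- t(sim)
  best_assignment(sim) / nrow(sim)
}

# maximum-sum one-to-one assignment of rows (the shorter side) to
# columns: exact enumeration for realistic component counts, greedy
# best-first beyond that (names with >4 components are degenerate input)
best_assignment <- function(sim) {
  k <- nrow(sim)
  m <- ncol(sim)
  if (k <= 4L && m <= 6L) {
    recurse <- function(row, used) {
      if (row > k) return(0)
      best <- -Inf
      for (col in seq_len(m)) {
        if (!used[col]) {
          used[col] <- TRUE
          best <- max(best, sim[row, col] + recurse(row + 1L, used))
          used[col] <- FALSE
        }
      }
      best
    }
    return(recurse(1L, logical(m)))
  }
  total <- 0
  for (step in seq_len(k)) {
    best <- arrayInd(which.max(sim), dim(sim))
    total <- total + sim[best[1L], best[2L]]
    sim[best[1L], ] <- -Inf
    sim[, best[2L]] <- -Inf
  }
  total
}

#' Date-part similarity
#'
#' Exact agreement of normalized date parts: 1 when equal, 0 otherwise,
#' `NA` when both empty. A date part either matches or it does not;
#' partial credit on digits would reward transcription noise.
#'
#' @param a,b normalized, zero-padded date parts.
#' @return numeric vector in `{0, 1}` with `NA` for both-empty pairs.
#' @export
similarity_datepart <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- as.numeric(a == b)
  out[!nzchar(a) & !nzchar(b)] <- NA_real_
  out[xor(nzchar(a), nzchar(b))] <- 0
  out
}

# one query value against a vector of candidates in a single adist()
# call; the workhorse of the population scan
sim_text_scan <- function(q, v) {
  out <- numeric(length(v))
  lq <- nchar(q)
  lv <- nchar(v)
  both_empty <- lq == 0L & lv == 0L
  out[both_empty] <- NA_real_
  live <- !both_empty
  if (any(live)) {
    d <- utils::adist(q, v[live])[1L, ]
    out[live] <- 1 - d / pmax(lq, lv[live])
  }
  out
}

# dispatch on field kind
field_similarity <- function(a, b, kind) {
  switch(kind,
         "name" = similarity_name(a, b),
         "date-part" = similarity_datepart(a, b),
         similarity_text(a, b))
}
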