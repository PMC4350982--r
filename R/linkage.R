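# EpiLink-style weighted record linkage.
#
# Each field i carries a weight w_i = log2((1 - e_i) / f_i), where e_i
# is the field's error (transcription) rate and f_i the average
# frequency of a value in the population: rare, reliably recorded
# fields discriminate strongly, error-prone or low-cardinality fields
# weakly.  Two records compare as
#
#     score = sum_i w_i * s_i / sum_i w_i
#
# over the fields present on both sides, with s_i the field similarity
# in [0, 1].  Two thresholds partition scores into MATCH (same person),
# NON_MATCH (new person) and the TENTATIVE band in between.

#' Field weight from error rate and value frequency
#'
#' `log2((1 - e) / f)`: the information content of an agreement on the
#' field. Requires `0 < e < 0.5`, `0 < f < 1` and `1 - e > f` so that
#' every configured field carries positive weight.
#'
#' @param e per-field error rate.
#' @param f average value frequency.
#' @return positive numeric weight.
#' @export
#' @examples
#' field_weight(0.01, 1 / 31) # a birth day
field_weight <- function(e, f) {
  if (any(e <= 0) || any(e >= 0.5) || any(f <= 0) || any(f >= 1) ||
      any(1 - e <= f)) {
    stop("field weights need 0 < e < 0.5, 0 < f < 1 and (1 - e) > f",
         call. = FALSE)
  }
  log2((1 - e) / f)
}

#' Default field schema
#'
#' The identifying attributes the patient list records by default:
#' first and last name (multi-component text) and the three parts of
#' the date of birth. All are required.
#'
#' @return a tibble with columns `name`, `kind`, `required`.
#' @export
default_schema <- function() {
  tibble::tibble(
    name = c("first_name", "last_name", "birth_day", "birth_month", "birth_year"),
    kind = c("name", "name", "date-part", "date-part", "date-part"),
    required = TRUE
  )
}

#' Linkage configuration
#'
#' Bundles the field schema, per-field error rates and value
#' frequencies (from which weights derive), the two decision
#' thresholds, and the exchange groups (sets of fields whose values are
#' commonly swapped at data entry — by default first and last name).
#'
#' Defaults: error rate 0.01 on every field; frequencies 5e-5
#' (first name), 1e-4 (last name), 1/31, 1/12, 1/90 (birth day, month,
#' year); thresholds 0.95 (match) and 0.60 (non-match).
#'
#' @param schema field schema tibble as from [default_schema()].
#' @param error_rate,frequency named numeric vectors keyed by field name.
#' @param t_match,t_nonmatch decision thresholds, `t_nonmatch < t_match`.
#' @param exchange_groups list of character vectors of mutually
#'   swappable field names (each of length 2).
#' @return an object of class `linkage_config`.
#' @export
#' @examples
#' cfg <- linkage_config()
#' cfg$weights
linkage_config <- function(schema = default_schema(),
                           error_rate = NULL,
                           frequency = NULL,
                           t_match = 0.95,
                           t_nonmatch = 0.60,
                           exchange_groups = list(c("first_name", "last_name"))) {
  default_e <- stats::setNames(rep(0.01, nrow(schema)), schema$name)
  default_f <- stats::setNames(rep(0.001, nrow(schema)), schema$name)
  builtin_f <- c(first_name = 5e-5, last_name = 1e-4,
                 birth_day = 1 / 31, birth_month = 1 / 12, birth_year = 1 / 90)
  default_f[intersect(names(default_f), names(builtin_f))] <-
    builtin_f[intersect(names(default_f), names(builtin_f))]
  e <- utils::modifyList(as.list(default_e), as.list(error_rate %||% list()))
  f <- utils::modifyList(as.list(default_f), as.list(frequency %||% list()))
  e <- unlist(e)[schema$name]
  f <- unlist(f)[schema$name]
  if (anyNA(e) || anyNA(f)) {
    stop("error_rate/frequency must cover every schema field", call. = FALSE)
  }
  if (!(t_nonmatch < t_match)) {
    stop("t_nonmatch must be strictly below t_match", call. = FALSE)
  }
  exchange_groups <- lapply(exchange_groups, as.character)
  for (g in exchange_groups) {
    if (length(g) != 2L || !all(g %in% schema$name)) {
      stop("exchange groups must name pairs of schema fields", call. = FALSE)
    }
  }
  w <- field_weight(e, f)
  structure(list(schema = schema, error_rate = e, frequency = f,
                 weights = w, t_match = t_match, t_nonmatch = t_nonmatch,
                 exchange_groups = exchange_groups),
            class = "linkage_config")
}

#' Print a linkage configuration
#' @param x a `linkage_config`.
#' @param ... unused.
#' @export
print.linkage_config <- function(x, ...) {
  cat("<linkage_config>\n")
  cat(sprintf("  fields: %s\n", paste(x$schema$name, collapse = ", ")))
  cat(sprintf("  weights: %s\n",
              paste(sprintf("%s=%.2f", names(x$weights), x$weights), collapse = " ")))
  cat(sprintf("  thresholds: match >= %.2f, non-match < %.2f\n",
              x$t_match, x$t_nonmatch))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-field similarities of one query against a population tibble of
# normalized fields; returns an n x n_fields numeric matrix
population_similarities <- function(query, population, schema) {
  n <- nrow(population)
  s <- matrix(NA_real_, n, nrow(schema), dimnames = list(NULL, schema$name))
  if (n == 0L) return(s)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    q <- query[[nm]]
    v <- population[[nm]]
    if (kind == "date-part") {
      s[, i] <- similarity_datepart(rep(q, n), v)
    } else if (kind == "name") {
      s[, i] <- sim_text_scan(q, v)
      # rows needing component assignment get the slower exact treatment
      idx <- if (grepl(" ", q, fixed = TRUE)) {
        which(nzchar(v))
      } else {
        which(grepl(" ", v, fixed = TRUE))
      }
      if (length(idx)) {
        s[idx, i] <- vapply(v[idx], similarity_name, 0, a = q,
                            USE.NAMES = FALSE)
      }
    } else {
      s[, i] <- sim_text_scan(q, v)
    }
    # a field empty on either side is not comparable: excluded from
    # both sums rather than scored 0, so sparse records are not biased
    # toward non-match
    s[!nzchar(v) | !nzchar(q %||% ""), i] <- NA_real_
  }
  s
}

# weighted mean over comparable fields, vectorised over rows of s
weighted_scores <- function(s, weights) {
  w <- matrix(weights, nrow(s), length(weights), byrow = TRUE)
  w[is.na(s)] <- 0
  s[is.na(s)] <- 0
  denom <- rowSums(w)
  num <- rowSums(w * s)
  ifelse(denom > 0, num / denom, 0)
}

# query with one exchange group's fields swapped
swap_fields <- function(record, group) {
  tmp <- record[[group[1L]]]
  record[[group[1L]]] <- record[[group[2L]]]
  record[[group[2L]]] <- tmp
  record
}

# scores of a query against every row of a normalized population tibble;
# the maximum over the identity assignment and each exchange-group swap
epilink_scores <- function(query, population, config) {
  if (nrow(population) == 0L) return(numeric(0))
  sc <- weighted_scores(
    population_similarities(query, population, config$schema), config$weights)
  for (g in config$exchange_groups) {
    swapped <- swap_fields(as.list(query), g)
    s_swap <- population_similarities(swapped, population, config$schema)
    # the swapped pairing can be weighted under either field's weight
    # (swap applied to the query or to the candidate); taking the max
    # of both keeps the score symmetric in its two records
    w_swap <- config$weights
    w_swap[g] <- w_swap[rev(g)]
    sc <- pmax(sc, weighted_scores(s_swap, config$weights),
               weighted_scores(s_swap, w_swap))
  }
  sc
}

#' EpiLink score of two records
#'
#' Weighted mean of per-field similarities over the fields present on
#' both records; fields empty on either side drop out of numerator and
#' denominator, so sparse records are not pushed toward non-match. With
#' exchange groups configured, the score is the maximum over the
#' identity assignment and each group's swap. Returns 0 when no field
#' is comparable.
#'
#' @param record_a,record_b named character vectors or lists of
#'   normalized field values (see [normalize_field()]).
#' @param config a [linkage_config()].
#' @return numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' cfg <- linkage_config()
#' a <- c(first_name = "IVAN PETER", last_name = "FELLEGI",
#'        birth_day = "22", birth_month = "06", birth_year = "1935")
#' b <- c(first_name = "IVAN", last_name = "FELLIGI",
#'        birth_day = "22", birth_month = "06", birth_year = "1935")
#' epilink_score(a, b, cfg)
epilink_score <- function(record_a, record_b, config = linkage_config()) {
  a <- as.list(record_a)
  missing_fields <- setdiff(config$schema$name, names(a))
  if (length(missing_fields)) {
    stop("record does not conform to the schema: missing ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  pop <- tibble::as_tibble(lapply(as.list(record_b)[config$schema$name],
                                  as.character))
  if (!all(config$schema$name %in% names(pop))) {
    stop("record does not conform to the schema", call. = FALSE)
  }
  epilink_scores(a, pop, config)
}

#' Best match of a query against a stored population
#'
#' Scores the query against every stored record (no blocking) and
#' classifies the best score with the two decision thresholds. Ties are
#' broken toward the earliest-created record, so results do not depend
#' on storage order quirks.
#'
#' @param query named list/vector of normalized field values.
#' @param population tibble of normalized records in creation order; may
#'   have zero rows.
#' @param config a [linkage_config()].
#' @param block_birth_year if `TRUE`, only candidates sharing the
#'   query's birth year are scored (an optional speed switch for large
#'   populations; off by default, and off in every shipped test).
#' @return a list with `index` (row in `population`, or `NA`), `score`,
#'   and `decision` (`"MATCH"`, `"TENTATIVE"`, or `"NON_MATCH"`).
#' @export
find_best_match <- function(query, population, config = linkage_config(),
                            block_birth_year = FALSE) {
  if (nrow(population) == 0L) {
    return(list(index = NA_integer_, score = 0, decision = "NON_MATCH"))
  }
  rows <- seq_len(nrow(population))
  if (block_birth_year && "birth_year" %in% names(population)) {
    rows <- which(population$birth_year == query[["birth_year"]])
    if (!length(rows)) {
      return(list(index = NA_integer_, score = 0, decision = "NON_MATCH"))
    }
  }
  sc <- epilink_scores(query, population[rows, , drop = FALSE], config)
  best <- which.max(sc) # first maximum = earliest created
  score <- sc[best]
  decision <- if (score >= config$t_match) "MATCH"
  else if (score >= config$t_nonmatch) "TENTATIVE"
  else "NON_MATCH"
  list(index = rows[best], score = unname(score), decision = decision)
}
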