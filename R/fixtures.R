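# Deterministic synthetic-IDAT generation and a typo model, so every
# linkage and end-to-end test runs without real patient data.
#
# What the generator emulates: a registry intake population of German
# names (umlauts included, occasionally a double first name) with valid
# birth dates, plus duplicates that differ from their source by
# realistic transcription noise — substituted, transposed, dropped or
# inserted characters.  What it does not emulate: real name-frequency
# distributions, households, or correlated field errors.

#' Typo model specification
#'
#' @param n_duplicates number of duplicates a benchmark derives.
#' @param typo_rate per-field probability that a field receives one
#'   typo operation.
#' @param typo_ops named probabilities of the four operations
#'   `substitution`, `transposition`, `deletion`, `insertion`; must sum
#'   to 1.
#' @param seed RNG seed; the same spec yields byte-identical output.
#' @return an object of class `corruption_spec`.
#' @export
corruption_spec <- function(n_duplicates = 0L,
                            typo_rate = 0.2,
                            typo_ops = c(substitution = 0.5,
                                         transposition = 0.2,
                                         deletion = 0.15,
                                         insertion = 0.15),
                            seed = 1L) {
  ops <- c("substitution", "transposition", "deletion", "insertion")
  if (!setequal(names(typo_ops), ops) || abs(sum(typo_ops) - 1) > 1e-9) {
    stop("typo_ops must assign probabilities summing to 1 to the four operations",
         call. = FALSE)
  }
  structure(list(n_duplicates = as.integer(n_duplicates),
                 typo_rate = typo_rate, typo_ops = typo_ops[ops],
                 seed = as.integer(seed)),
            class = "corruption_spec")
}

# days per month, leap-agnostic conservative (Feb capped at 28)
DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Generate a synthetic IDAT population
#'
#' Draws `n` records from the bundled name pools with valid calendar
#' birth dates uniform over 1920–2010. About 8% of first names are
#' double names ("Ivan Peter" style). Records are guaranteed pairwise
#' distinct in at least two of the five fields, so no two generated
#' base records can be confused by exact agreement on all but one
#' field. Fully deterministic under `seed`.
#'
#' @param n number of records.
#' @param seed RNG seed.
#' @return a tibble with columns `first_name`, `last_name`,
#'   `birth_day`, `birth_month`, `birth_year` (all character, raw
#'   i.e. un-normalized values).
#' @export
#' @examples
#' generate_population(3, seed = 42)
generate_population <- function(n, seed = 1L) {
  stopifnot(n >= 0)
  empty <- tibble::tibble(first_name = character(0), last_name = character(0),
                          birth_day = character(0), birth_month = character(0),
                          birth_year = character(0))
  if (n == 0L) return(empty)
  withr::local_seed(seed)
  draw <- function(m) {
    fn <- sample(FIRST_NAME_POOL, m, replace = TRUE)
    dbl <- stats::runif(m) < 0.08
    fn[dbl] <- paste(fn[dbl], sample(FIRST_NAME_POOL, sum(dbl), replace = TRUE))
    mo <- sample(12L, m, replace = TRUE)
    tibble::tibble(
      first_name = fn,
      last_name = sample(LAST_NAME_POOL, m, replace = TRUE),
      birth_day = as.character(vapply(mo, function(x)
        sample(DAYS_IN_MONTH[x], 1L), 1L)),
      birth_month = as.character(mo),
      birth_year = as.character(sample(1920:2010, m, replace = TRUE))
    )
  }
  pop <- draw(n)
  # resample rows that agree with an earlier row on 4+ fields: a pair
  # may share at most 3 of the 5 fields
  repeat {
    clash <- rep(FALSE, nrow(pop))
    cols <- names(pop)
    for (drop_col in cols) {
      key <- do.call(paste, c(pop[setdiff(cols, drop_col)], sep = "\r"))
      clash <- clash | duplicated(key)
    }
    if (!any(clash)) break
    pop[clash, ] <- draw(sum(clash))
  }
  pop
}

TYPO_LETTERS <- LETTERS
TYPO_DIGITS <- as.character(0:9)

# apply one typo operation to a string; returns list(value, op, position)
apply_typo <- function(x, op, numeric_field) {
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  pool <- if (numeric_field) TYPO_DIGITS else TYPO_LETTERS
  if (n == 0L) {
    return(list(value = sample(pool, 1L), op = "insertion", position = 1L))
  }
  if (op == "transposition" && n < 2L) op <- "substitution"
  if (op == "deletion" && n < 2L) op <- "substitution"
  switch(op,
    substitution = {
      pos <- sample(n, 1L)
      repl <- sample(setdiff(pool, toupper(chars[pos])), 1L)
      if (chars[pos] %in% letters) repl <- tolower(repl)
      chars[pos] <- repl
      list(value = paste(chars, collapse = ""), op = op, position = pos)
    },
    transposition = {
      distinct <- which(toupper(chars[-n]) != toupper(chars[-1L]))
      if (!length(distinct)) {
        return(apply_typo(x, "substitution", numeric_field))
      }
      pos <- if (length(distinct) == 1L) distinct else sample(distinct, 1L)
      chars[c(pos, pos + 1L)] <- chars[c(pos + 1L, pos)]
      list(value = paste(chars, collapse = ""), op = op, position = pos)
    },
    deletion = {
      pos <- sample(n, 1L)
      list(value = paste(chars[-pos], collapse = ""), op = op, position = pos)
    },
    insertion = {
      pos <- sample(n + 1L, 1L)
      ins <- sample(pool, 1L)
      if (any(chars %in% letters)) ins <- tolower(ins)
      list(value = paste(append(chars, ins, after = pos - 1L), collapse = ""),
           op = op, position = pos)
    }
  )
}

#' Corrupt a record with transcription noise
#'
#' Applies at most one typo operation to each field, independently with
#' probability `spec$typo_rate`. `typo_rate = 0` returns the record
#' unchanged. The returned edit log records exactly the fields changed.
#'
#' @param record a one-row tibble or named list with the schema fields.
#' @param spec a [corruption_spec()]; its `seed` is *not* re-applied
#'   here — seed control belongs to the caller (see
#'   [make_linkage_benchmark()]), so corrupting a stream of records
#'   stays deterministic as a whole.
#' @param force_field if non-`NULL`, corrupt exactly this one field
#'   (used for the guaranteed single-typo duplicates of benchmarks).
#' @param force_op optionally force the operation kind.
#' @param force_position,force_char optionally pin substitution
#'   position and replacement character.
#' @return a list with `record` (mutated) and `edits` (tibble of
#'   `field`, `op`, `position`).
#' @export
corrupt_record <- function(record, spec = corruption_spec(),
                           force_field = NULL, force_op = NULL,
                           force_position = NULL, force_char = NULL) {
  rec <- as.list(record)
  fields <- names(rec)
  edits <- list()
  targets <- if (!is.null(force_field)) {
    stopifnot(force_field %in% fields)
    force_field
  } else {
    fields[stats::runif(length(fields)) < spec$typo_rate]
  }
  for (f in targets) {
    numeric_field <- grepl("birth", f)
    if (!is.null(force_position)) {
      chars <- strsplit(rec[[f]], "")[[1]]
      chars[force_position] <- force_char
      rec[[f]] <- paste(chars, collapse = "")
      edits[[length(edits) + 1L]] <-
        tibble::tibble(field = f, op = "substitution",
                       position = as.integer(force_position))
      next
    }
    op <- force_op %||% sample(names(spec$typo_ops), 1L, prob = spec$typo_ops)
    r <- apply_typo(rec[[f]], op, numeric_field)
    if (!identical(r$value, rec[[f]])) {
      rec[[f]] <- r$value
      edits[[length(edits) + 1L]] <-
        tibble::tibble(field = f, op = r$op, position = as.integer(r$position))
    }
  }
  list(record = tibble::as_tibble(rec),
       edits = if (length(edits)) dplyr::bind_rows(edits) else
         tibble::tibble(field = character(0), op = character(0),
                        position = integer(0)))
}

#' Build a linkage benchmark with known ground truth
#'
#' Emits `n_base` base records plus `n_dup` corrupted duplicates (each
#' derived from a distinct base record by exactly one typo in one
#' randomly chosen field) together with the true duplicate pairs.
#' Optionally writes the records as CSV (UTF-8, stable column order)
#' and the truth pairs as JSON.
#'
#' @param n_base,n_dup counts, `n_dup <= n_base`.
#' @param spec a [corruption_spec()]; supplies the seed and typo model.
#' @param csv,truth optional output file paths.
#' @return a list with `records` (tibble of `n_base + n_dup` rows),
#'   `truth` (two-column matrix of row indices: base, duplicate), and
#'   `edits` (edit log tibble).
#' @export
make_linkage_benchmark <- function(n_base, n_dup, spec = corruption_spec(),
                                   csv = NULL, truth = NULL) {
  stopifnot(n_dup <= n_base)
  base <- generate_population(n_base, seed = spec$seed)
  withr::local_seed(spec$seed + 1L)
  dup_src <- sort(sample(n_base, n_dup))
  dups <- vector("list", n_dup)
  edits <- vector("list", n_dup)
  for (i in seq_len(n_dup)) {
    if (spec$typo_rate == 0) {
      # noise-free benchmark: duplicates are exact copies
      dups[[i]] <- base[dup_src[i], ]
      edits[[i]] <- NULL
      next
    }
    field <- sample(names(base), 1L)
    r <- corrupt_record(base[dup_src[i], ], spec, force_field = field)
    # the odd operation is a no-op (e.g. swapping equal characters);
    # redraw until a visible edit exists so the ground truth really is
    # "one typo in one field"
    while (nrow(r$edits) == 0L) {
      field <- sample(names(base), 1L)
      r <- corrupt_record(base[dup_src[i], ], spec, force_field = field)
    }
    dups[[i]] <- r$record
    edits[[i]] <- dplyr::mutate(r$edits, duplicate_row = n_base + i)
  }
  records <- dplyr::bind_rows(base, dplyr::bind_rows(dups))
  truth_pairs <- cbind(base = dup_src, duplicate = n_base + seq_len(n_dup))
  if (!is.null(csv)) {
    utils::write.csv(records, csv, row.names = FALSE, fileEncoding = "UTF-8")
  }
  if (!is.null(truth)) {
    jsonlite::write_json(apply(truth_pairs, 1L, identity, simplify = FALSE),
                         truth)
  }
  list(records = records, truth = truth_pairs,
       edits = if (n_dup) dplyr::bind_rows(edits) else NULL)
}

#' Evaluate linkage quality on a benchmark
#'
#' Normalizes all records, then (a) links every duplicate against the
#' base population and (b) scores every base-against-base pair. A
#' duplicate counts as recalled when its best match is its true source
#' record and the decision is not `NON_MATCH` — with two thresholds,
#' TENTATIVE is the designed outcome for heavier typos, and what
#' matters is that the duplicate is not silently accepted as a new
#' person. A false merge is a `MATCH` between two base records that
#' differ in all five fields.
#'
#' @param benchmark result of [make_linkage_benchmark()].
#' @param config a [linkage_config()].
#' @return a one-row tibble: `n_base`, `n_dup`, `recall`,
#'   `n_recalled`, `false_merges`, plus the duplicate score summary
#'   columns `score_min`, `score_mean`.
#' @export
evaluate_linkage <- function(benchmark, config = linkage_config()) {
  records <- benchmark$records
  truth <- benchmark$truth
  n_base <- nrow(records) - nrow(truth)
  norm <- normalize_population(records, config$schema)
  base_norm <- norm[seq_len(n_base), ]

  # (a) duplicate recall
  hits <- logical(nrow(truth))
  scores <- numeric(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    q <- as.list(norm[truth[i, "duplicate"], ])
    m <- find_best_match(q, base_norm, config)
    scores[i] <- m$score
    hits[i] <- !is.na(m$index) && m$index == truth[i, "base"] &&
      m$decision != "NON_MATCH"
  }

  # (b) false merges among base records differing in all fields
  false_merges <- 0L
  for (i in seq_len(n_base)) {
    sc <- epilink_scores(as.list(base_norm[i, ]),
                         base_norm[-seq_len(i), , drop = FALSE], config)
    cand <- which(sc >= config$t_match)
    for (j in cand) {
      other <- base_norm[i + j, ]
      differs_all <- all(vapply(config$schema$name, function(nm)
        !identical(base_norm[[nm]][i], other[[nm]][[1]]), TRUE))
      if (differs_all) false_merges <- false_merges + 1L
    }
  }

  tibble::tibble(
    n_base = n_base, n_dup = nrow(truth),
    recall = mean(hits), n_recalled = sum(hits),
    false_merges = false_merges,
    score_min = if (length(scores)) min(scores) else NA_real_,
    score_mean = if (length(scores)) mean(scores) else NA_real_
  )
}

#' Normalize a population tibble
#'
#' Applies [normalize_field()] column-wise and prepends the
#' `internal_id` / `tentative` bookkeeping columns, yielding the shape
#' [find_best_match()] scans.
#'
#' @param records tibble of raw records with the schema's columns.
#' @param schema field schema tibble.
#' @return a normalized population tibble.
#' @export
normalize_population <- function(records, schema = default_schema()) {
  out <- records[schema$name]
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    out[[nm]] <- normalize_field(records[[nm]], schema$kind[i],
                                 datepart_width(nm))
  }
  tibble::as_tibble(c(list(internal_id = seq_len(nrow(out)),
                           tentative = rep(FALSE, nrow(out))), out))
}

#' Plot the score separation of a benchmark
#'
#' Histogram of duplicate-to-source scores against the decision
#' thresholds: a quick visual check that the typo model keeps true
#' pairs inside the accept region. Requires ggplot2.
#'
#' @param benchmark result of [make_linkage_benchmark()].
#' @param config a [linkage_config()].
#' @return a ggplot object.
#' @export
plot_linkage_scores <- function(benchmark, config = linkage_config()) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is needed for plotting", call. = FALSE)
  }
  norm <- normalize_population(benchmark$records, config$schema)
  n_base <- nrow(benchmark$records) - nrow(benchmark$truth)
  scores <- vapply(seq_len(nrow(benchmark$truth)), function(i) {
    epilink_scores(as.list(norm[benchmark$truth[i, "duplicate"], ]),
                   norm[benchmark$truth[i, "base"], , drop = FALSE],
                   config)
  }, 0)
  df <- tibble::tibble(score = scores)
  ggplot2::ggplot(df, ggplot2::aes(x = score)) +
    ggplot2::geom_histogram(binwidth = 0.01, fill = "grey35") +
    ggplot2::geom_vline(xintercept = c(config$t_nonmatch, config$t_match),
                        linetype = "dashed") +
    ggplot2::labs(x = "EpiLink score of true duplicate pairs", y = "pairs",
                  title = "Duplicate score separation",
                  subtitle = "dashed: non-match / match thresholds") +
    ggplot2::theme_minimal()
}
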