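# Field preprocessing, string similarities, and the weighted
# two-threshold linkage decision.

test_that("normalization trims, collapses, transliterates and pads", {
  expect_identical(normalize_field("  Müller ", "name"), "MUELLER")
  expect_identical(normalize_field("ivan  peter", "name"), "IVAN PETER")
  expect_identical(normalize_field("7", "date-part", width = 2), "07")
  expect_identical(normalize_field("1935", "date-part", width = 4), "1935")
  expect_identical(normalize_field("Großkreutz", "name"), "GROSSKREUTZ")
  expect_identical(normalize_field("Noël", "name"), "NOEL")
  expect_identical(normalize_field("", "name"), "")
  expect_identical(normalize_field(c("Jörg", " da  Silva "), "name"),
                   c("JOERG", "DA SILVA"))
})

test_that("text similarity is normalized Levenshtein with empty handling", {
  expect_equal(similarity_text("FELLEGI", "FELLIGI"), 1 - 1 / 7)
  expect_equal(similarity_text("ABC", "ABC"), 1)
  expect_equal(similarity_text("A", "B"), 0)
  expect_true(is.na(similarity_text("", "")))
  expect_equal(similarity_text("", "X"), 0)
  # symmetry and agreement with a textbook DP implementation
  set.seed(4)
  for (i in 1:25) {
    a <- normalize_field(sample(LAST_NAME_POOL_TEST, 1), "name")
    b <- normalize_field(sample(LAST_NAME_POOL_TEST, 1), "name")
    s <- similarity_text(a, b)
    expect_equal(s, similarity_text(b, a))
    expect_equal(s, 1 - oracle_levenshtein(a, b) / max(nchar(a), nchar(b)))
  }
})

test_that("name similarity assigns components one-to-one, extras free", {
  expect_equal(similarity_name("IVAN PETER", "IVAN"), 1)
  expect_equal(similarity_name("ANNA MARIA", "MARIA ANNA"), 1)
  expect_equal(similarity_name("IVAN", "IVAN"), 1)
  expect_true(is.na(similarity_name("", "")))
  # agreement with the exhaustive permutation oracle on <= 3 components
  set.seed(8)
  for (i in 1:60) {
    a <- paste(sample(FIRST_NAME_POOL_TEST, sample(1:3, 1)), collapse = " ")
    b <- paste(sample(FIRST_NAME_POOL_TEST, sample(1:3, 1)), collapse = " ")
    a <- normalize_field(a, "name")
    b <- normalize_field(b, "name")
    expect_equal(similarity_name(a, b), oracle_name_similarity(a, b))
  }
})

test_that("date-part similarity is exact agreement", {
  expect_equal(similarity_datepart("1935", "1935"), 1)
  expect_equal(similarity_datepart("06", "07"), 0)
  expect_equal(similarity_datepart("22", "22"), 1)
  expect_true(is.na(similarity_datepart("", "")))
  expect_equal(similarity_datepart("", "07"), 0)
})

test_that("field weights follow log2((1-e)/f) and its monotonicity", {
  expect_equal(field_weight(0.01, 0.00001), log2(99000))
  expect_equal(field_weight(0.01, 0.00001), 16.595, tolerance = 1e-4)
  eps <- 1e-6
  expect_lt(field_weight(0.5 - eps, 0.5 - eps), 1e-4)
  # decreasing in both arguments
  expect_gt(field_weight(0.01, 0.001), field_weight(0.02, 0.001))
  expect_gt(field_weight(0.01, 0.001), field_weight(0.01, 0.002))
  expect_error(field_weight(0.6, 0.1))
  expect_error(field_weight(0.01, 1.5))
  expect_error(field_weight(0.4, 0.8)) # weight would be negative
})

test_that("identical records score 1 and the worked example is a match", {
  cfg <- linkage_config()
  a <- c(first_name = "IVAN PETER", last_name = "FELLEGI",
         birth_day = "22", birth_month = "06", birth_year = "1935")
  b <- c(first_name = "IVAN", last_name = "FELLIGI",
         birth_day = "22", birth_month = "06", birth_year = "1935")
  expect_equal(epilink_score(a, a, cfg), 1)
  s <- epilink_score(a, b, cfg)
  expect_gte(s, cfg$t_match)
  # hand recomputation: names 1.0 and 6/7, dates exact
  w <- cfg$weights
  expect_equal(s, (w[["first_name"]] + w[["last_name"]] * 6 / 7 +
                     w[["birth_day"]] + w[["birth_month"]] + w[["birth_year"]]) /
                 sum(w))
})

test_that("the score equals a straight-line recomputation on random pairs", {
  cfg <- linkage_config()
  set.seed(21)
  pop <- generate_population(100, seed = 77)
  norm <- lapply(seq_len(nrow(pop)), function(i) {
    vapply(names(pop), function(nm) {
      normalize_field(pop[[nm]][i],
                      cfg$schema$kind[match(nm, cfg$schema$name)],
                      if (grepl("year", nm)) 4L else 2L)
    }, "")
  })
  for (rep in 1:100) {
    ij <- sample(100, 2)
    a <- norm[[ij[1]]]
    b <- norm[[ij[2]]]
    # independent arithmetic: per-field similarities, two assignments
    score_one <- function(x, y) {
      s <- c(similarity_name(x[["first_name"]], y[["first_name"]]),
             similarity_name(x[["last_name"]], y[["last_name"]]),
             similarity_datepart(x[["birth_day"]], y[["birth_day"]]),
             similarity_datepart(x[["birth_month"]], y[["birth_month"]]),
             similarity_datepart(x[["birth_year"]], y[["birth_year"]]))
      w <- unname(cfg$weights)
      keep <- !is.na(s)
      sum(w[keep] * s[keep]) / sum(w[keep])
    }
    swap_a <- a
    swap_a[c("first_name", "last_name")] <- a[c("last_name", "first_name")]
    swap_b <- b
    swap_b[c("first_name", "last_name")] <- b[c("last_name", "first_name")]
    expected <- max(score_one(a, b), score_one(swap_a, b), score_one(a, swap_b))
    expect_equal(epilink_score(a, b, cfg), expected)
  }
})

test_that("scores stay in [0,1], are symmetric, and react to swapped names", {
  cfg <- linkage_config()
  set.seed(5)
  pop <- generate_population(40, seed = 13)
  recs <- lapply(seq_len(nrow(pop)), function(i) {
    r <- as.list(pop[i, ])
    vapply(cfg$schema$name, function(nm)
      normalize_field(r[[nm]], cfg$schema$kind[match(nm, cfg$schema$name)],
                      if (grepl("year", nm)) 4L else 2L), "")
  })
  for (i in 1:40) {
    a <- recs[[sample(40, 1)]]
    b <- recs[[sample(40, 1)]]
    s <- epilink_score(a, b, cfg)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_equal(s, epilink_score(b, a, cfg))
  }
  # swapping first/last name is absorbed by the exchange group
  a <- recs[[1]]
  sw <- a
  sw[c("first_name", "last_name")] <- a[c("last_name", "first_name")]
  expect_equal(epilink_score(a, sw, cfg), 1)
})

test_that("improving one field similarity never lowers the score", {
  cfg <- linkage_config(exchange_groups = list())
  base <- c(first_name = "MARTIN", last_name = "WAGNER",
            birth_day = "03", birth_month = "11", birth_year = "1960")
  # last-name variants ordered by similarity to WAGNER
  variants <- c("KRAUSE", "WEGNER", "WAGNER")
  sims <- similarity_text(rep("WAGNER", 3), variants)
  expect_true(all(diff(sims) > 0))
  scores <- vapply(variants, function(ln) {
    other <- base
    other[["last_name"]] <- ln
    epilink_score(base, other, cfg)
  }, 0)
  expect_true(all(diff(scores) > 0))
})

test_that("missing fields drop out of both sums instead of penalizing", {
  cfg <- linkage_config()
  a <- c(first_name = "ANNA", last_name = "SCHMIDT",
         birth_day = "01", birth_month = "02", birth_year = "1970")
  sparse <- a
  sparse[["birth_day"]] <- ""
  sparse[["birth_month"]] <- ""
  expect_equal(epilink_score(a, sparse, cfg), 1)
  none <- c(first_name = "", last_name = "", birth_day = "",
            birth_month = "", birth_year = "")
  expect_equal(epilink_score(none, none, cfg), 0)
  expect_error(epilink_score(c(first_name = "X"), a, cfg), "schema")
})

test_that("find_best_match returns the brute-force argmax with thresholds", {
  cfg <- linkage_config()
  empty <- normalize_population(generate_population(0), cfg$schema)
  expect_identical(find_best_match(list(first_name = "A", last_name = "B",
                                        birth_day = "01", birth_month = "01",
                                        birth_year = "1990"),
                                   empty, cfg)$decision, "NON_MATCH")

  pop <- normalize_population(generate_population(500, seed = 31), cfg$schema)
  q <- as.list(pop[137, setdiff(names(pop), c("internal_id", "tentative"))])
  m <- find_best_match(q, pop, cfg)
  expect_identical(m$index, 137L)
  expect_equal(m$score, 1)
  expect_identical(m$decision, "MATCH")

  # brute-force scan with the scalar scorer on a corrupted query
  set.seed(9)
  qc <- q
  qc$last_name <- paste0(qc$last_name, "X")
  scores <- vapply(seq_len(nrow(pop)), function(i)
    epilink_score(qc, as.list(pop[i, ]), cfg), 0)
  m2 <- find_best_match(qc, pop, cfg)
  expect_identical(m2$index, which.max(scores))
  expect_equal(m2$score, max(scores))
  band <- function(s) if (s >= cfg$t_match) "MATCH"
    else if (s >= cfg$t_nonmatch) "TENTATIVE" else "NON_MATCH"
  expect_identical(m2$decision, band(max(scores)))
})

test_that("ties break toward the earliest-created record", {
  cfg <- linkage_config()
  rec <- c(first_name = "ERIKA", last_name = "VOGEL",
           birth_day = "09", birth_month = "09", birth_year = "1955")
  pop <- normalize_population(
    tibble::tibble(first_name = "Erika", last_name = "Vogel",
                   birth_day = "09", birth_month = "09",
                   birth_year = "1955")[c(1, 1), ], cfg$schema)
  m <- find_best_match(as.list(rec), pop, cfg)
  expect_identical(m$index, 1L)
})
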