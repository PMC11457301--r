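test_that("co-occurrence rows count synonym unions correctly", {
  corpus <- ldi_corpus(dplyr::bind_rows(
    make_pub("P1", abstract = "DHB was used", methods = "MALDI"),
    make_pub("P2", abstract = "2,5-dihydroxybenzoic acid as matrix",
             methods = "MALDI"),
    make_pub("P3", abstract = "DHB in solution"),
    make_pub("P4", abstract = "nothing relevant")
  ))
  subs <- tibble::tibble(name = "2,5-dihydroxybenzoic acid",
                         synonyms = list("DHB"))
  tab <- build_cooccurrence_table(corpus, subs, query_term("MALDI"))
  # union over synonyms in disjoint publication sets
  expect_equal(tab$total, 3)
  expect_equal(tab$with_technique, 2)
  expect_equal(tab$technique_fraction, 2 / 3)

  # brute-force oracle over the synonym OR
  brute <- sum(vapply(1:4, function(i) {
    oracle_match(corpus$publications[i, ],
                 query_or(query_term("2,5-dihydroxybenzoic acid"),
                          query_term("DHB")))
  }, logical(1)))
  expect_equal(tab$total, brute)
})

test_that("absent substances yield undefined (not zero) ratios", {
  corpus <- tiny_corpus()
  tab <- build_cooccurrence_table(
    corpus, tibble::tibble(name = "unobtainium", synonyms = list(character(0))),
    query_term("MALDI"))
  expect_equal(tab$total, 0)
  expect_true(is.na(tab$technique_fraction))
  expect_true(is.na(tab$sm_pp))
})

test_that("rows are sorted by technique co-occurrence, descending", {
  gen <- generate_corpus(generator_config(n_publications = 300, seed = 9))
  tab <- build_cooccurrence_table(gen$corpus, gen$truth$substances,
                                  technique_queries()$MALDI)
  expect_false(is.unsorted(rev(tab$with_technique)))
})

test_that("background rate matches hand arithmetic", {
  # three substances with fractions 0.5%, 1.0%, 1.5%
  mk <- function(id, n_total, n_tech, word) {
    dplyr::bind_rows(lapply(seq_len(n_total), function(i) {
      make_pub(sprintf("%s%04d", id, i), abstract = word,
               methods = if (i <= n_tech) "MALDI" else "plain text")
    }))
  }
  corpus <- ldi_corpus(dplyr::bind_rows(
    mk("A", 200, 1, "adenosine"),   # 0.5%
    mk("B", 100, 1, "glucose"),     # 1.0%
    mk("C", 200, 3, "nicotine")     # 1.5%
  ))
  subs <- tibble::tibble(name = c("adenosine", "glucose", "nicotine"),
                         synonyms = list(character(0), character(0),
                                         character(0)))
  bg <- background_rate(corpus, subs, query_term("MALDI", field = "methods"))
  expect_equal(bg$mean_percent, 1.0)
  expect_equal(bg$sd_percent, 0.5)
  expect_equal(bg$n_substances, 3)
})

test_that("background rate excludes unmatched substances with a warning", {
  corpus <- tiny_corpus()
  subs <- tibble::tibble(name = c("protein", "polymer", "unobtainium"),
                         synonyms = list(character(0), character(0),
                                         character(0)))
  expect_warning(bg <- background_rate(corpus, subs, query_term("MALDI")),
                 "unobtainium")
  expect_equal(bg$n_substances, 2)
})

test_that("the 5x / >=10 enrichment rule behaves at its boundaries", {
  rows <- tibble::tibble(
    substance = c("always", "half-but-rare", "common-but-dilute"),
    total = c(13L, 18L, 1000L),
    with_technique = c(13L, 9L, 20L),
    with_sm = 0L, with_pp = 0L, with_op = 0L
  )
  rows$technique_fraction <- context_ratio(rows$with_technique, rows$total)
  rows$sm_pp <- NA_real_
  rows$sm_op <- NA_real_
  out <- flag_enriched(rows, background = 1.0)
  expect_equal(out$enriched, c(TRUE, FALSE, FALSE))

  # monotone: raising with_technique at fixed total never un-flags
  rows2 <- rows
  rows2$with_technique <- pmin(rows2$with_technique + 5L, rows2$total)
  rows2$technique_fraction <- context_ratio(rows2$with_technique, rows2$total)
  out2 <- flag_enriched(rows2, background = 1.0)
  expect_true(all(out2$enriched >= out$enriched))
})

test_that("context ratios are undefined only on zero denominators", {
  expect_equal(context_ratio(0, 5), 0)
  expect_true(is.na(context_ratio(3, 0)))
  expect_equal(context_ratio(c(1, 2), c(2, 0)), c(0.5, NA))
})

test_that("pooled weighted average has the documented invariances", {
  rows <- tibble::tibble(
    substance = c("a", "b"),
    total = c(10L, 10L), with_technique = c(5L, 6L),
    with_sm = c(1L, 3L), with_pp = c(2L, 3L), with_op = c(1L, 1L)
  )
  expect_equal(pooled_weighted_average(rows, "sm_pp"), 4 / 5)

  single <- rows[1, ]
  expect_equal(pooled_weighted_average(single, "sm_pp"),
               single$with_sm / single$with_pp)

  # invariant to row order and to splitting a row with the same sums
  expect_equal(pooled_weighted_average(rows[2:1, ], "sm_pp"),
               pooled_weighted_average(rows, "sm_pp"))
  split_rows <- tibble::tibble(
    substance = c("a", "b1", "b2"),
    total = c(10L, 5L, 5L), with_technique = c(5L, 3L, 3L),
    with_sm = c(1L, 2L, 1L), with_pp = c(2L, 1L, 2L), with_op = c(1L, 0L, 1L)
  )
  expect_equal(pooled_weighted_average(split_rows, "sm_pp"),
               pooled_weighted_average(rows, "sm_pp"))

  # pooled result lies within the per-row ratio range
  r <- context_ratio(rows$with_sm, rows$with_pp)
  pooled <- pooled_weighted_average(rows, "sm_pp")
  expect_gte(pooled, min(r))
  expect_lte(pooled, max(r))

  # all-zero denominators are undefined
  zero <- rows
  zero$with_pp <- 0L
  expect_true(is.na(pooled_weighted_average(zero, "sm_pp")))
})

test_that("expected ratio and excess-over-expected arithmetic", {
  expect_equal(expected_ratio(7, 7), 1.000)
  expect_error(expected_ratio(1, 0), "positive")
  expect_equal(excess_over_expected(0.5, 0.5), 0)
  expect_equal(excess_over_expected(0.548, 0.450), 21.777778,
               tolerance = 1e-6)
})
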