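test_that("generation is byte-identical for a fixed seed", {
  g1 <- generate_corpus(generator_config(n_publications = 60, seed = 11))
  g2 <- generate_corpus(generator_config(n_publications = 60, seed = 11))
  expect_equal(g1$corpus$publications, g2$corpus$publications)
  expect_equal(g1$corpus$entities, g2$corpus$entities)
  expect_equal(g1$truth$mention_flags, g2$truth$mention_flags)

  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(g1$corpus, p1)
  write_corpus(g2$corpus, p2)
  expect_identical(readLines(p1), readLines(p2))

  g3 <- generate_corpus(generator_config(n_publications = 60, seed = 12))
  expect_false(identical(g1$corpus$publications$abstract,
                         g3$corpus$publications$abstract))
})

test_that("invalid configurations fail before any sampling", {
  expect_error(generator_config(n_publications = 0), "n_publications")
  expect_error(generator_config(technique_prevalence = c(MALDI = 1.3)),
               "probabilities")
  expect_error(generator_config(year_provenance_probs = c(pubYear = 1)),
               "year_provenance_probs")
  expect_error(analyte_class("x", 10, log(100), 0, 0, 1, 1), "mw_sdlog")
})

test_that("text injection is lossless: query engine reproduces ground truth", {
  gen <- generate_corpus(generator_config(n_publications = 400, seed = 23))
  corpus <- gen$corpus
  truth <- gen$truth
  tq <- technique_queries()
  for (t in colnames(truth$technique_flags)) {
    expect_identical(eval_query(corpus, tq[[t]]),
                     unname(truth$technique_flags[, t]))
  }
  ctx <- default_context_queries()
  for (c in c("sm", "pp", "op")) {
    expect_identical(eval_query(corpus, ctx[[c]]),
                     unname(truth$context_flags[, c]))
  }
  subs <- truth$substances
  for (i in seq_len(nrow(subs))) {
    q <- lditrends:::substance_query(subs$name[i], subs$synonyms[[i]])
    expect_identical(eval_query(corpus, q),
                     unname(truth$mention_flags[, subs$name[i]]),
                     info = subs$name[i])
  }
})

test_that("realized joint counts never exceed marginals", {
  gen <- generate_corpus(generator_config(n_publications = 300, seed = 5))
  ts <- truth_summary(gen$truth)
  expect_true(all(ts$with_technique <= ts$total))
  expect_true(all(ts$with_sm <= ts$with_technique))
  expect_true(all(ts$with_pp <= ts$with_technique))
  expect_true(all(ts$with_op <= ts$with_technique))
  expect_true(all(ts$total <= n_publications(gen$corpus)))
})

test_that("truth_summary handles degenerate corpora", {
  gen <- generate_corpus(generator_config(n_publications = 1, seed = 3))
  ts <- truth_summary(gen$truth)
  expect_true(all(ts$total %in% 0:1))
  expect_true(all(is.na(ts$technique_fraction[ts$total == 0])))
})

test_that("conditional mention probabilities are recovered at 3 SE", {
  cfg <- generator_config(n_publications = 4000, seed = 77)
  gen <- generate_corpus(cfg)
  truth <- gen$truth
  subs <- truth$substances
  t <- truth$technique_flags[, "MALDI"]
  n_t <- sum(t)
  for (i in which(subs$kind == "matrix")[1:4]) {
    p1 <- truth$p_mention_given_technique[[subs$name[i]]]
    phat <- mean(truth$mention_flags[t, subs$name[i]])
    se <- sqrt(p1 * (1 - p1) / n_t)
    expect_lt(abs(phat - p1), 3 * se + 1e-12,
              label = paste("P(mention|technique) for", subs$name[i]))
  }
})

test_that("generated analyte properties match configured moments at 3 SE", {
  cfg <- generator_config(n_publications = 50, seed = 19)
  gen <- generate_corpus(cfg)
  ent <- gen$corpus$entities
  for (cl in cfg$analyte_classes) {
    rows <- grepl(paste0("synthetic-", cl$name), ent$name)
    k <- sum(rows)
    mu_mw <- exp(cl$mw_meanlog + cl$mw_sdlog^2 / 2)
    sd_mw <- mu_mw * sqrt(exp(cl$mw_sdlog^2) - 1)
    expect_lt(abs(mean(ent$mw[rows]) - mu_mw), 3 * sd_mw / sqrt(k))
    expect_lt(abs(mean(ent$logp[rows]) - cl$logp_mean),
              3 * cl$logp_sd / sqrt(k))
  }
})

test_that("citation counts are age-proportional with a flat per-age score", {
  cfg <- generator_config(n_publications = 6000, seed = 31)
  gen <- generate_corpus(cfg)
  truth <- gen$truth
  age <- truth$year$age
  per_age <- truth$citations$citations / age
  # regression of citations-per-age on age has slope ~ 0
  fit <- stats::lm(per_age ~ age)
  slope <- summary(fit)$coefficients["age", ]
  expect_lt(abs(slope["Estimate"]), 3 * slope["Std. Error"] + 1e-9)
  # and the mean recovers the configured rate
  expect_equal(mean(per_age), cfg$citations_per_year, tolerance = 0.1)
})
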