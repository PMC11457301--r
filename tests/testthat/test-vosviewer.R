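test_that("year resolution follows the field order with provenance", {
  p <- make_pub("A", pub_year = 2015)
  expect_equal(resolve_year(p), list(year = 2015L, provenance = "pubYear"))

  p <- make_pub("B", first_pub_date = "2012-03-01",
                first_index_date = "2013-01-01")
  expect_equal(resolve_year(p),
               list(year = 2012L, provenance = "first_pub_date"))

  p <- make_pub("C", journal_year = 2010, electronic_pub_date = "2008-01-01")
  expect_equal(resolve_year(p),
               list(year = 2010L, provenance = "journal_year"))

  p <- make_pub("D")
  expect_equal(resolve_year(p),
               list(year = 2006L, provenance = "imputed_median"))

  # unparseable date treated as absent, with warning
  p <- make_pub("E", first_pub_date = "not-a-date",
                first_index_date = "2019-05-05")
  expect_warning(out <- resolve_year(p), "unparseable")
  expect_equal(out$provenance, "first_index_date")
  expect_equal(out$year, 2019L)
})

test_that("scores impute zero citations and clamp age to one year", {
  p <- make_pub("A", pub_year = 2018)
  s <- compute_scores(p, reference_year = 2023)
  expect_equal(s$citations, 0L)
  expect_equal(s$citations_per_age, 0)

  p <- make_pub("B", pub_year = 2018, cited_by_count = 10)
  expect_equal(compute_scores(p, 2023)$citations_per_age, 2.0)

  p <- make_pub("C", pub_year = 2023, cited_by_count = 4)
  expect_equal(compute_scores(p, 2023)$citations_per_age, 4.0)
})

test_that("scores files are complete, aligned and round-trippable", {
  corpus <- tiny_corpus()
  records <- score_records(corpus, reference_year = 2023)
  path <- withr::local_tempfile(fileext = ".txt")
  write_scores_file(records, path)
  lines <- readLines(path)
  expect_length(lines, nrow(records) + 1)  # header + one row each
  expect_match(lines[1], "^id\t")

  back <- utils::read.delim(path, check.names = FALSE)
  expect_equal(back$id, records$pub_id)
  expect_equal(back[["publication year"]], records$resolved_year)
  expect_equal(back$citations, records$citations)
  expect_equal(back[["citations per year"]], records$citations_per_age,
               tolerance = 1e-6)
  # the all-absent-year record is present via imputation, no missing cells
  expect_false(any(is.na(as.matrix(back))))

  cpath <- withr::local_tempfile(fileext = ".txt")
  write_corpus_file(corpus, cpath, records)
  expect_length(readLines(cpath), nrow(records))

  misaligned <- records[c(2, 1, 3), ]
  expect_error(write_corpus_file(corpus, cpath, misaligned), "align")
})

test_that("corpus files sanitize embedded tabs and keep empty abstracts", {
  corpus <- ldi_corpus(dplyr::bind_rows(
    make_pub("A", title = "has\ttab", abstract = "line\nbreak"),
    make_pub("B", title = "plain", abstract = NA)
  ))
  path <- withr::local_tempfile(fileext = ".txt")
  write_corpus_file(corpus, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  expect_equal(lengths(strsplit(lines, "\t")), c(2, 1))  # B: empty abstract
  expect_false(grepl("has\ttab", lines[1], fixed = TRUE))
})

test_that("thesaurus files map excluded terms to empty replacements", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_thesaurus(c("january", "france", "january"), path)
  lines <- readLines(path)
  expect_equal(lines[1], "label\treplace by")
  expect_length(lines, 3)  # deduplicated
  expect_equal(lines[2], "january\t")

  write_thesaurus(character(0), path)
  expect_length(readLines(path), 1)

  expect_gt(length(default_excluded_terms()), 20)
})

test_that("occurrence thresholds scale with corpus size, floor 1", {
  expect_equal(normalized_min_occurrences(10478, 10478, 10), 10)
  expect_equal(normalized_min_occurrences(500, 10478, 10), 1)
  expect_error(normalized_min_occurrences(10, 0), "base_n")
})

test_that("provenance frequencies on a synthetic corpus match exactly", {
  gen <- generate_corpus(generator_config(n_publications = 800, seed = 13))
  records <- score_records(gen$corpus, reference_year = 2023)
  expect_identical(records$year_provenance, gen$truth$year$provenance)
  expect_identical(records$resolved_year, gen$truth$year$resolved_year)
  # realized citations flow through, absent ones as zero
  truth_cites <- ifelse(gen$truth$citations$missing, 0L,
                        gen$truth$citations$citations)
  expect_identical(records$citations, truth_cites)
})
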