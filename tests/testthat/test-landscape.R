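landscape_fixture <- function() {
  # two pubs, three entities in known property positions
  ent <- tibble::tibble(
    chebi_id = c("CHEBI:1", "CHEBI:2", "CHEBI:3"),
    name = c("low", "high", "matrixy"),
    formula = c(NA, "C6H12O6", NA),
    smiles = c(NA_character_, NA, NA),
    roles = list(character(0), character(0), "MALDI matrix material"),
    mw = c(100, NA, 250),
    logp = c(0.2, -2.1, 2.4)
  )
  mk_ann <- function(ids, counts) {
    tibble::tibble(chebi_id = ids, term = ids, count = counts)
  }
  pubs <- dplyr::bind_rows(
    make_pub("P1", abstract = "a", methods = "MALDI mass spectrometry"),
    make_pub("P2", abstract = "b", methods = "MALDI mass spectrometry"),
    make_pub("P3", abstract = "no technique here")
  )
  pubs$annotations <- list(
    mk_ann(c("CHEBI:1", "CHEBI:2"), c(2L, 1L)),
    mk_ann(c("CHEBI:1", "CHEBI:3"), c(1L, 3L)),
    mk_ann("CHEBI:2", 5L)
  )
  ldi_corpus(pubs, ent)
}

test_that("property points aggregate papers and recognitions per entity", {
  corpus <- landscape_fixture()
  pts <- property_points(corpus)
  pts <- pts[order(pts$chebi_id), ]
  expect_equal(pts$chebi_id, c("CHEBI:1", "CHEBI:2", "CHEBI:3"))
  expect_equal(pts$n_papers, c(2L, 2L, 1L))
  expect_equal(pts$n_recognitions, c(3L, 6L, 3L))
  # mw falls back to the formula when no explicit value is present
  expect_equal(pts$mw[pts$chebi_id == "CHEBI:2"], compute_mw("C6H12O6"))
  expect_true(all(pts$n_recognitions >= pts$n_papers))
})

test_that("a technique slice restricts the annotation pool", {
  corpus <- landscape_fixture()
  pts <- property_points(corpus, technique = 'METHODS:MALDI')
  expect_equal(sort(pts$chebi_id), c("CHEBI:1", "CHEBI:2", "CHEBI:3"))
  expect_equal(pts$n_recognitions[pts$chebi_id == "CHEBI:2"], 1L)
})

test_that("matrix-role filtering removes exactly the role bearers", {
  corpus <- landscape_fixture()
  pts <- property_points(corpus)
  expect_message(kept <- filter_matrix_role(pts, corpus$entities),
                 "removed 1")
  expect_equal(nrow(kept), nrow(pts) - 1)
  expect_false("CHEBI:3" %in% kept$chebi_id)

  # no role bearers: identity
  none <- pts[pts$chebi_id != "CHEBI:3", ]
  expect_message(kept2 <- filter_matrix_role(none, corpus$entities),
                 "removed 0")
  expect_equal(kept2, none)
})

test_that("grid weights are conserved and out-of-range points reported", {
  corpus <- landscape_fixture()
  g <- build_landscape(corpus)
  expect_equal(sum(g$weights), g$totals$paper_chebi_pairs)
  expect_equal(g$out_of_range$points, 0)

  # shrink the grid so one point falls outside
  g2 <- build_landscape(corpus, bins = list(logp = seq(-1, 3, 0.5),
                                            mw = seq(0, 1500, 25)))
  expect_equal(g2$out_of_range$points, 1)
  expect_equal(sum(g2$weights) + g2$out_of_range$weight,
               g2$totals$paper_chebi_pairs)
})

test_that("equal-logP families land in a single grid column", {
  n <- 12
  ent <- tibble::tibble(
    chebi_id = sprintf("CHEBI:%d", seq_len(n)),
    name = sprintf("oligo%02d", seq_len(n)),
    formula = NA_character_, smiles = NA_character_,
    roles = replicate(n, character(0), simplify = FALSE),
    mw = seq(180, 1100, length.out = n),  # spread over many mw bins
    logp = rep(-2.3, n)
  )
  pubs <- make_pub("P1", abstract = "x")
  pubs$annotations <- list(tibble::tibble(chebi_id = ent$chebi_id,
                                          term = ent$name,
                                          count = rep(1L, n)))
  g <- build_landscape(ldi_corpus(pubs, ent))
  col_sums <- rowSums(g$weights)  # rows index logP bins
  expect_equal(sum(col_sums > 0), 1)  # a single vertical line
})

test_that("weighting modes coincide when every count is one", {
  corpus <- landscape_fixture()
  pubs <- corpus$publications
  pubs$annotations <- lapply(pubs$annotations, function(a) {
    a$count <- rep(1L, nrow(a))
    a
  })
  corpus1 <- ldi_corpus(pubs, corpus$entities)
  ga <- build_landscape(corpus1, weighting = "paper_chebi_pairs")
  gb <- build_landscape(corpus1, weighting = "recognitions")
  expect_equal(ga$weights, gb$weights)
})

test_that("filtering before binning equals cell-wise subtraction after", {
  corpus <- landscape_fixture()
  pts <- property_points(corpus)
  suppressMessages({
    g_filtered <- build_landscape(corpus, drop_matrix_role = TRUE)
  })
  g_all <- build_landscape(corpus)
  role_pts <- pts[pts$chebi_id == "CHEBI:3", ]
  g_role <- build_landscape(role_pts)
  expect_equal(g_filtered$weights, g_all$weights - g_role$weights)
})

test_that("property summaries average correctly under each weighting", {
  pts <- tibble::tibble(chebi_id = c("a", "b"), mw = c(100, 300),
                        logp = c(0, 1), n_papers = c(1L, 1L),
                        n_recognitions = c(1L, 3L))
  expect_equal(property_summary(pts, "paper_chebi_pairs"),
               c(mean_mw = 200.00, mean_logp = 0.50))
  expect_equal(property_summary(pts, "recognitions"),
               c(mean_mw = 250.00, mean_logp = 0.75))
  expect_equal(property_summary(pts[1, ], "unique"),
               c(mean_mw = 100, mean_logp = 0))
  expect_true(all(is.na(property_summary(pts[0, ]))))
})

test_that("empty slices produce an empty grid with zero totals", {
  corpus <- landscape_fixture()
  g <- build_landscape(corpus, technique = '"unmatched phrase"')
  expect_equal(g$totals$unique_chebis, 0)
  expect_equal(sum(g$weights), 0)
})

test_that("landscape TSV and sidecar round-trip the grid", {
  corpus <- landscape_fixture()
  g <- build_landscape(corpus)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(g, path)
  tab <- utils::read.delim(path)
  expect_equal(sum(tab$weight), sum(g$weights))
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path))
  expect_equal(side$totals$paper_chebi_pairs, g$totals$paper_chebi_pairs)
  expect_equal(side$weighting, g$weighting)
})
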