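# Matrix co-occurrence enrichment. For each candidate matrix substance we
# count the publications mentioning it (any synonym, any text field), those
# that also match the technique query, and those that additionally match the
# small-molecule (SM), peptide/protein (PP) and oligomer/polymer (OP)
# context queries. A substance is flagged as enriched when its technique
# co-occurrence fraction is at least `fold` times the background rate
# established from common non-matrix chemicals AND it co-occurs in at least
# `min_count` publications (defaults 5x / >= 10).

#' Shipped substance lists
#'
#' The default substance lists: 19 literature-curated MALDI matrix
#' substances (with synonyms and curation flags) and the 10 common
#' non-matrix chemicals used to establish the background co-occurrence rate
#' (adenosine, alanine, ascorbic acid, chlorophyll, cholesterol, cisplatin,
#' cocaine, glucose, nicotine, water).
#'
#' @param group `"matrix"`, `"nonmatrix"`, or `"all"`.
#' @return Tibble with columns `name`, `synonyms` (list-column), `group`,
#'   `is_curated_matrix`.
#' @export
ldi_substances <- function(group = c("all", "matrix", "nonmatrix")) {
  group <- match.arg(group)
  path <- system.file("extdata", "matrix_substances.tsv",
                      package = "lditrends", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  tab <- tibble(
    name = raw$name,
    synonyms = lapply(strsplit(raw$synonyms, ";", fixed = TRUE),
                      function(s) s[nzchar(trimws(s))]),
    chebi_id = ifelse(nzchar(raw$chebi_id), raw$chebi_id, NA_character_),
    group = raw$group,
    is_curated_matrix = raw$is_curated_matrix == "TRUE"
  )
  if (group != "all") tab <- tab[tab$group == group, ]
  tab
}

#' Published matrix co-occurrence reference table
#'
#' The 19 matrix substances that pass the enrichment rule against the live
#' literature (queries of 2023-10-01), with their publication counts,
#' technique co-occurrences and SM/PP, SM/OP context ratios. Shipped as a
#' static resource for desk-scale checks of the enrichment arithmetic.
#'
#' @return Tibble with columns `substance`, `with_technique`, `total`,
#'   `sm_pp`, `sm_op`, `is_curated_matrix`.
#' @export
matrix_reference_table <- function() {
  path <- system.file("extdata", "matrix_cooccurrence_reference.tsv",
                      package = "lditrends", mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  tibble(
    substance = raw$substance,
    with_technique = as.integer(raw$with_technique),
    total = as.integer(raw$total),
    sm_pp = raw$sm_pp,
    sm_op = raw$sm_op,
    is_curated_matrix = raw$is_curated_matrix
  )
}

#' Default analyte-context queries
#'
#' The three context queries used alongside a technique query: "small
#' molecule(s)" (SM), "peptide(s) or protein(s)" (PP) and "oligomer(s) or
#' polymer(s)" (OP), all unrestricted (title + abstract + methods) and
#' plural-inclusive.
#'
#' @return Named list of `ldi_query` nodes (`sm`, `pp`, `op`).
#' @export
default_context_queries <- function() {
  list(
    sm = parse_query('"small molecule" OR "small molecules"'),
    pp = parse_query("peptide OR peptides OR protein OR proteins"),
    op = parse_query("oligomer OR oligomers OR polymer OR polymers")
  )
}

substance_query <- function(name, synonyms) {
  terms <- unique(c(name, synonyms))
  terms <- terms[nzchar(trimws(terms))]
  if (!length(terms)) {
    stop("substance '", name, "' has no searchable synonyms", call. = FALSE)
  }
  nodes <- lapply(terms, query_term, field = "all")
  if (length(nodes) == 1L) nodes[[1L]] else do.call(query_or, nodes)
}

#' Build the substance/technique co-occurrence table
#'
#' For each substance, counts publications mentioning any synonym (substance
#' queries are not METHODS-restricted), the co-occurrences with the
#' technique query, and the three-way co-occurrences with each analyte
#' context. Rows are sorted by technique co-occurrence, descending. Ratios
#' with a zero denominator are `NA` (undefined), never zero.
#'
#' @param corpus An `ldi_corpus`.
#' @param substances Tibble with `name` and a `synonyms` list-column (see
#'   [ldi_substances()]), or a character vector of names.
#' @param technique An `ldi_query` (or query string) for the technique.
#' @param contexts Named list of context queries (`sm`, `pp`, `op`).
#' @return Tibble with one row per substance: `substance`, `total`,
#'   `with_technique`, `with_sm`, `with_pp`, `with_op`,
#'   `technique_fraction`, `sm_pp`, `sm_op`.
#' @export
build_cooccurrence_table <- function(corpus, substances, technique,
                                     contexts = default_context_queries()) {
  if (is.character(substances)) {
    substances <- tibble(name = substances,
                         synonyms = replicate(length(substances),
                                              character(0), simplify = FALSE))
  }
  if (is.character(technique)) technique <- parse_query(technique)
  stopifnot(all(c("sm", "pp", "op") %in% names(contexts)))

  tech <- eval_query(corpus, technique)
  sm <- eval_query(corpus, contexts$sm)
  pp <- eval_query(corpus, contexts$pp)
  op <- eval_query(corpus, contexts$op)

  rows <- lapply(seq_len(nrow(substances)), function(i) {
    hit <- eval_query(corpus,
                      substance_query(substances$name[i],
                                      substances$synonyms[[i]]))
    tibble(
      substance = substances$name[i],
      total = sum(hit),
      with_technique = sum(hit & tech),
      with_sm = sum(hit & tech & sm),
      with_pp = sum(hit & tech & pp),
      with_op = sum(hit & tech & op)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$technique_fraction <- context_ratio(out$with_technique, out$total)
  out$sm_pp <- context_ratio(out$with_sm, out$with_pp)
  out$sm_op <- context_ratio(out$with_sm, out$with_op)
  out[order(-out$with_technique, out$substance), ]
}

#' Background technique co-occurrence rate
#'
#' The fraction of publications mentioning each common non-matrix chemical
#' that also match the technique query, summarized as a mean and sample
#' standard deviation in percent. Substances matching no publication are
#' excluded with a warning (their fraction is undefined).
#'
#' @param corpus An `ldi_corpus`.
#' @param substances Non-matrix substance tibble or character vector
#'   (default: the shipped 10-chemical baseline).
#' @param technique Technique query.
#' @return An object of class `ldi_background` with `mean_percent`,
#'   `sd_percent`, `n_substances` and per-substance `fractions`.
#' @export
background_rate <- function(corpus, substances = ldi_substances("nonmatrix"),
                            technique) {
  tab <- build_cooccurrence_table(corpus, substances, technique)
  absent <- tab$total == 0
  if (any(absent)) {
    warning("excluding substance(s) with no matching publications: ",
            paste(tab$substance[absent], collapse = ", "), call. = FALSE)
    tab <- tab[!absent, ]
  }
  if (nrow(tab) < 2) {
    stop("background rate needs at least two substances with matches",
         call. = FALSE)
  }
  pct <- 100 * tab$with_technique / tab$total
  structure(
    list(
      mean_percent = mean(pct),
      sd_percent = stats::sd(pct),
      n_substances = nrow(tab),
      fractions = tibble(substance = tab$substance, total = tab$total,
                         with_technique = tab$with_technique, percent = pct)
    ),
    class = "ldi_background"
  )
}

#' @export
print.ldi_background <- function(x, ...) {
  cat(sprintf("<ldi_background> %.2f +/- %.2f%% over %d substances\n",
              x$mean_percent, x$sd_percent, x$n_substances))
  invisible(x)
}

#' Flag enriched substances
#'
#' A substance is enriched when its technique co-occurrence fraction
#' (`with_technique / total`) is at least `fold` times the background mean
#' and it co-occurs with the technique in at least `min_count` publications.
#' Rows with an undefined fraction (no matching publications) are never
#' flagged.
#'
#' @param rows Co-occurrence table from [build_cooccurrence_table()].
#' @param background An `ldi_background`, or a numeric background mean in
#'   percent.
#' @param fold Enrichment fold threshold (default 5).
#' @param min_count Minimum technique co-occurrence count (default 10).
#' @return `rows` with a logical `enriched` column added.
#' @export
flag_enriched <- function(rows, background, fold = 5, min_count = 10) {
  bg_pct <- if (inherits(background, "ldi_background")) {
    background$mean_percent
  } else {
    as.numeric(background)
  }
  if (!is.finite(bg_pct) || bg_pct <= 0) {
    stop("background mean must be positive", call. = FALSE)
  }
  frac <- rows$technique_fraction
  rows$enriched <- !is.na(frac) &
    frac >= fold * bg_pct / 100 &
    rows$with_technique >= min_count
  rows
}

#' Ratio of two co-occurrence counts
#'
#' `numerator / denominator`, with a zero denominator yielding `NA`
#' (undefined), never an exception and never zero.
#'
#' @param numerator,denominator Non-negative counts (vectorized).
#' @return Numeric vector.
#' @export
context_ratio <- function(numerator, denominator) {
  ifelse(denominator == 0, NA_real_, numerator / denominator)
}

#' Pooled weighted average of a context ratio
#'
#' The default `"pooled"` mode computes the ratio of summed counts,
#' sum(SM) / sum(PP) (weights are the denominator counts), which reduces to
#' the row's own ratio for a single row and is invariant to splitting a row
#' into parts with the same totals. The alternative `"row_weighted"` mode
#' averages per-row ratios weighted by each row's technique co-occurrence
#' count.
#'
#' @param rows Co-occurrence table from [build_cooccurrence_table()].
#' @param context `"sm_pp"` or `"sm_op"`.
#' @param mode `"pooled"` (default) or `"row_weighted"`.
#' @return Numeric scalar, `NA` if every denominator is zero.
#' @export
pooled_weighted_average <- function(rows, context = c("sm_pp", "sm_op"),
                                    mode = c("pooled", "row_weighted")) {
  context <- match.arg(context)
  mode <- match.arg(mode)
  den_col <- if (context == "sm_pp") "with_pp" else "with_op"
  if (mode == "pooled") {
    den <- sum(rows[[den_col]])
    if (den == 0) return(NA_real_)
    sum(rows$with_sm) / den
  } else {
    r <- context_ratio(rows$with_sm, rows[[den_col]])
    ok <- !is.na(r) & rows$with_technique > 0
    if (!any(ok)) return(NA_real_)
    stats::weighted.mean(r[ok], rows$with_technique[ok])
  }
}

#' Naively expected context ratio from corpus sizes
#'
#' The ratio of the sizes of two technique corpora, e.g. the number of
#' small-molecule MALDI publications over the number of peptide/protein
#' MALDI publications, reported to 3 decimals.
#'
#' @param n_context_a,n_context_b Corpus sizes.
#' @return Numeric scalar.
#' @export
#' @examples
#' expected_ratio(10478, 80806) # 0.130
#' expected_ratio(10478, 23288) # 0.450
expected_ratio <- function(n_context_a, n_context_b) {
  if (any(n_context_b <= 0)) stop("denominator must be positive", call. = FALSE)
  round(n_context_a / n_context_b, 3)
}

#' Excess of an observed ratio over the expected ratio
#'
#' `100 * (weighted - expected) / expected`, in percent.
#'
#' @param weighted Observed (weighted-average) ratio.
#' @param expected Naively expected ratio; must be positive.
#' @return Percent excess.
#' @export
#' @examples
#' excess_over_expected(0.208, 0.130) # 60
excess_over_expected <- function(weighted, expected) {
  if (any(expected <= 0)) stop("expected ratio must be positive", call. = FALSE)
  100 * (weighted - expected) / expected
}
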