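# VOSviewer input files. VOSviewer consumes plain tab-separated corpus and
# scores files and does not accept missing values, so export applies the
# imputation cascade: the publication year is taken from the first present
# field among pubYear, the journal year of publication, the first
# publication date, the electronic publication date and the first index
# date (date fields contribute their year component); if all five are
# absent the median publication year across Europe PMC/PubMed, 2006, is
# imputed. Missing citation counts are imputed as zero. A third score,
# citations per year of age, highlights "hot" topics.

YEAR_PROVENANCE <- c("pubYear", "journal_year", "first_pub_date",
                     "electronic_pub_date", "first_index_date",
                     "imputed_median")

year_from_date <- function(x) {
  if (is.na(x)) return(NA_integer_)
  m <- regmatches(x, regexpr("^[0-9]{4}", x))
  if (!length(m)) return(NA_integer_)
  as.integer(m)
}

#' Resolve a publication year with provenance
#'
#' Walks the year fields in their resolution order -- `pub_year`,
#' `journal_year`, `first_pub_date`, `electronic_pub_date`,
#' `first_index_date` -- and returns the first present value together with a
#' provenance label. Date fields contribute their year component. A present
#' but unparseable value is treated as absent, with a warning. If all five
#' fields are absent the fallback year is returned with provenance
#' `"imputed_median"`.
#'
#' @param pub A one-row slice of `corpus$publications` or a list with the
#'   year fields.
#' @param fallback Year imputed when every field is absent (default 2006,
#'   the median publication year across Europe PMC and PubMed).
#' @return List with elements `year` (integer) and `provenance` (one of
#'   `pubYear`, `journal_year`, `first_pub_date`, `electronic_pub_date`,
#'   `first_index_date`, `imputed_median`).
#' @export
resolve_year <- function(pub, fallback = 2006L) {
  get_int <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x)) return(NA_integer_)
    as.integer(x)
  }
  get_date_year <- function(x, what) {
    if (is.null(x) || length(x) == 0 || is.na(x)) return(NA_integer_)
    y <- year_from_date(x)
    if (is.na(y)) {
      warning("unparseable ", what, " '", x, "' treated as absent",
              call. = FALSE)
    }
    y
  }
  candidates <- list(
    pubYear = get_int(pub$pub_year),
    journal_year = get_int(pub$journal_year),
    first_pub_date = get_date_year(pub$first_pub_date, "first_pub_date"),
    electronic_pub_date = get_date_year(pub$electronic_pub_date,
                                        "electronic_pub_date"),
    first_index_date = get_date_year(pub$first_index_date, "first_index_date")
  )
  for (name in names(candidates)) {
    if (!is.na(candidates[[name]])) {
      return(list(year = candidates[[name]], provenance = name))
    }
  }
  list(year = as.integer(fallback), provenance = "imputed_median")
}

#' Per-publication VOSviewer scores
#'
#' Resolves the publication year, imputes missing citation counts as zero,
#' and computes the citations-per-age score with the age in whole years
#' clamped to at least 1 (so same-year publications never divide by zero).
#'
#' @param pub A one-row slice of `corpus$publications` or an equivalent list.
#' @param reference_year Year the corpus was retrieved (age is measured
#'   against it).
#' @param fallback_year Imputation fallback passed to [resolve_year()].
#' @return List with `pub_id`, `resolved_year`, `year_provenance`,
#'   `citations`, `citations_per_age`.
#' @export
compute_scores <- function(pub, reference_year = 2023L,
                           fallback_year = 2006L) {
  ry <- resolve_year(pub, fallback = fallback_year)
  cites <- pub$cited_by_count
  cites <- if (is.null(cites) || length(cites) == 0 || is.na(cites)) 0L
           else as.integer(cites)
  age <- max(as.integer(reference_year) - ry$year, 1L)
  list(
    pub_id = pub$pub_id,
    resolved_year = ry$year,
    year_provenance = ry$provenance,
    citations = cites,
    citations_per_age = cites / age
  )
}

#' Score records for a whole corpus
#'
#' @param corpus An `ldi_corpus`.
#' @param reference_year,fallback_year See [compute_scores()].
#' @return Tibble with one row per publication, in corpus order.
#' @export
score_records <- function(corpus, reference_year = 2023L,
                          fallback_year = 2006L) {
  pubs <- corpus$publications
  rows <- lapply(seq_len(nrow(pubs)), function(i) {
    as_tibble(compute_scores(pubs[i, ], reference_year, fallback_year))
  })
  dplyr::bind_rows(rows)
}

sanitize_cell <- function(x) {
  x <- ifelse(is.na(x), "", x)
  gsub("[\t\r\n]+", " ", x)
}

#' Write a VOSviewer scores file
#'
#' Tab-separated with header `id`, `publication year`, `citations`,
#' `citations per year`; one row per publication and no missing cells
#' (VOSviewer rejects missing values -- any unresolved score aborts the
#' write, naming the offending record).
#'
#' @param records Score tibble from [score_records()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_file <- function(records, path) {
  if (!nrow(records)) stop("no score records to write", call. = FALSE)
  bad <- !stats::complete.cases(records[c("resolved_year", "citations",
                                          "citations_per_age")])
  if (any(bad)) {
    stop("unresolved scores for publication(s): ",
         paste(records$pub_id[bad], collapse = ", "), call. = FALSE)
  }
  lines <- c(
    "id\tpublication year\tcitations\tcitations per year",
    sprintf("%s\t%d\t%d\t%.6g", records$pub_id, records$resolved_year,
            records$citations, records$citations_per_age)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a VOSviewer corpus file
#'
#' One tab-separated `title<TAB>abstract` row per publication, aligned
#' row-by-row with the scores file. Embedded tabs and newlines are
#' sanitized to spaces; an empty abstract keeps its (empty) column.
#'
#' @param corpus An `ldi_corpus`.
#' @param path Output path.
#' @param records Optional score tibble; when given, row alignment with the
#'   corpus is checked and an error raised on mismatch.
#' @return `path`, invisibly.
#' @export
write_corpus_file <- function(corpus, path, records = NULL) {
  pubs <- corpus$publications
  if (!is.null(records) &&
      (nrow(records) != nrow(pubs) ||
       !identical(records$pub_id, pubs$pub_id))) {
    stop("corpus file rows do not align with the scores file", call. = FALSE)
  }
  lines <- paste0(sanitize_cell(pubs$title), "\t",
                  sanitize_cell(pubs$abstract))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a VOSviewer thesaurus file
#'
#' Maps each excluded term (names of months, countries and other
#' uninformative words) to an empty replacement, which removes it from the
#' term map. Duplicates are dropped.
#'
#' @param excluded_terms Character vector of terms to exclude; defaults to
#'   the shipped month/country list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(excluded_terms = default_excluded_terms(), path) {
  terms <- unique(excluded_terms)
  lines <- "label\treplace by"
  if (length(terms)) lines <- c(lines, paste0(terms, "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default excluded thesaurus terms
#' @return Character vector (months and country names).
#' @export
default_excluded_terms <- function() {
  path <- system.file("extdata", "thesaurus_terms.txt",
                      package = "lditrends", mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

#' Corpus-size-normalized minimum term occurrences
#'
#' Scales a base minimum-occurrence threshold by relative corpus size:
#' `round(base_threshold * n_pubs / base_n)` (half-up), clamped to at least
#' 1. With the base threshold 10 on a 10478-publication corpus, an
#' 80806-publication corpus gets a threshold of 77.
#'
#' @param n_pubs Number of publications matching the query of interest.
#' @param base_n Size of the reference corpus.
#' @param base_threshold Threshold used for the reference corpus.
#' @return Integer threshold, at least 1.
#' @export
#' @examples
#' normalized_min_occurrences(80806, 10478, 10) # 77
normalized_min_occurrences <- function(n_pubs, base_n, base_threshold = 10L) {
  if (base_n < 1) stop("base_n must be at least 1", call. = FALSE)
  max(1L, as.integer(floor(base_threshold * n_pubs / base_n + 0.5)))
}
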