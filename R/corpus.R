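#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Publications are stored as one tibble row per record; annotations as a
# list-column of per-publication tibbles (chebi_id, term, count). Text and
# metadata fields that are absent in the input stay NA -- they are never
# defaulted at load time, because imputation (year cascade, zero citations)
# is an export-time rule, not an ingestion rule.

PUB_COLUMNS <- c(
  "pub_id", "title", "abstract", "methods_text",
  "pub_year", "journal_year",
  "first_pub_date", "electronic_pub_date", "first_index_date",
  "cited_by_count"
)

empty_annotations <- function() {
  tibble(chebi_id = character(), term = character(), count = integer())
}

empty_entities <- function() {
  tibble(
    chebi_id = character(), name = character(), formula = character(),
    smiles = character(), roles = list(), mw = numeric(), logp = numeric()
  )
}

#' Construct a corpus object
#'
#' A corpus bundles publication records, the chemical-entity table that
#' resolves their ChEBI annotations, and any annotation rows that referenced
#' unknown publications ("orphans").
#'
#' @param publications Tibble with columns `pub_id`, `title`, `abstract`,
#'   `methods_text`, `pub_year`, `journal_year`, `first_pub_date`,
#'   `electronic_pub_date`, `first_index_date`, `cited_by_count`, and a
#'   list-column `annotations`.
#' @param entities Tibble of chemical entities (see [read_entities()]).
#' @param orphans Tibble of annotation rows that could not be attached.
#' @return An object of class `ldi_corpus`.
#' @export
ldi_corpus <- function(publications, entities = empty_entities(),
                       orphans = NULL) {
  publications <- as_tibble(publications)
  if (!"annotations" %in% names(publications)) {
    publications$annotations <- replicate(nrow(publications),
                                          empty_annotations(),
                                          simplify = FALSE)
  }
  validate_publications(publications)
  structure(
    list(
      publications = publications,
      entities = as_tibble(entities),
      orphans = orphans %||%
        tibble(pub_id = character(), chebi_id = character(),
               term = character(), count = integer()),
      .index = new.env(parent = emptyenv())
    ),
    class = "ldi_corpus"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_publications <- function(pubs, line_of = NULL) {
  id <- pubs$pub_id
  bad <- which(is.na(id) | !nzchar(id))
  if (length(bad)) {
    stop("publication ", locate_record(bad[1], line_of),
         " has an empty pub_id", call. = FALSE)
  }
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate pub_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  ymax <- as.integer(format(Sys.Date(), "%Y"))
  for (col in c("pub_year", "journal_year")) {
    y <- pubs[[col]]
    bad <- which(!is.na(y) & (y < 1900L | y > ymax))
    if (length(bad)) {
      stop("record ", locate_record(bad[1], line_of), ": ", col, " ", y[bad[1]],
           " outside [1900, ", ymax, "]", call. = FALSE)
    }
  }
  bad <- which(!is.na(pubs$cited_by_count) & pubs$cited_by_count < 0)
  if (length(bad)) {
    stop("record ", locate_record(bad[1], line_of),
         ": negative cited_by_count", call. = FALSE)
  }
  invisible(pubs)
}

locate_record <- function(i, line_of) {
  if (is.null(line_of)) i else paste0("at line ", line_of[i])
}

#' Number of publications in a corpus
#' @param corpus An `ldi_corpus`.
#' @export
n_publications <- function(corpus) nrow(corpus$publications)

#' @export
print.ldi_corpus <- function(x, ...) {
  cat("<ldi_corpus> ", nrow(x$publications), " publications, ",
      nrow(x$entities), " entities, ",
      sum(vapply(x$publications$annotations, nrow, 0L)), " annotations\n",
      sep = "")
  invisible(x)
}

# ---- JSONL record I/O ------------------------------------------------------

# One record per line with the Europe PMC core field names, so archived API
# output is ingestible unchanged:
#   id, title, abstract, methods, pubYear, journalInfo.yearOfPublication,
#   firstPublicationDate, electronicPublicationDate, firstIndexDate,
#   citedByCount
# Empty strings and missing keys are both treated as absent.

field_or_na <- function(rec, key, as = "character") {
  v <- rec[[key]]
  if (is.null(v) || length(v) == 0 || is.na(v)[1] || identical(as.character(v), "")) {
    return(switch(as, character = NA_character_, integer = NA_integer_))
  }
  if (as == "integer") {
    iv <- suppressWarnings(as.integer(v))
    if (is.na(iv)) stop("field '", key, "' is not an integer: ", v)
    return(iv)
  }
  as.character(v)
}

parse_record <- function(line, lineno) {
  rec <- tryCatch(
    jsonlite::fromJSON(line, simplifyVector = TRUE),
    error = function(e) {
      stop("malformed record at line ", lineno, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  jy <- rec$journalInfo$yearOfPublication %||% rec$journalYearOfPublication
  ann <- empty_annotations()
  if (!is.null(rec$annotations) && length(rec$annotations)) {
    a <- as_tibble(rec$annotations)
    ann <- tibble(chebi_id = as.character(a$chebi_id),
                  term = as.character(a$term),
                  count = as.integer(a$count))
  }
  tryCatch(
    tibble(
      pub_id = field_or_na(rec, "id"),
      title = field_or_na(rec, "title"),
      abstract = field_or_na(rec, "abstract"),
      methods_text = field_or_na(rec, "methods"),
      pub_year = field_or_na(rec, "pubYear", "integer"),
      journal_year = field_or_na(list(y = jy), "y", "integer"),
      first_pub_date = field_or_na(rec, "firstPublicationDate"),
      electronic_pub_date = field_or_na(rec, "electronicPublicationDate"),
      first_index_date = field_or_na(rec, "firstIndexDate"),
      cited_by_count = field_or_na(rec, "citedByCount", "integer"),
      annotations = list(ann)
    ),
    error = function(e) {
      stop("malformed record at line ", lineno, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
}

#' Read a publication corpus from a line-delimited record file
#'
#' Each line holds one JSON record in the Europe PMC core-field dialect
#' (`id`, `title`, `abstract`, `methods`, `pubYear`,
#' `journalInfo.yearOfPublication`, `firstPublicationDate`,
#' `electronicPublicationDate`, `firstIndexDate`, `citedByCount`, optional
#' `annotations`). Missing and empty-string fields are preserved as absent,
#' never defaulted: downstream stages own all imputation rules.
#'
#' @param path Path to a JSONL record file (UTF-8).
#' @return An [ldi_corpus()].
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  rows <- Map(parse_record, lines[keep], which(keep))
  pubs <- if (length(rows)) dplyr::bind_rows(rows) else
    dplyr::bind_rows(tibble(pub_id = character(), title = character(),
                            abstract = character(), methods_text = character(),
                            pub_year = integer(), journal_year = integer(),
                            first_pub_date = character(),
                            electronic_pub_date = character(),
                            first_index_date = character(),
                            cited_by_count = integer(),
                            annotations = list()))
  validate_publications(pubs, line_of = which(keep))
  ldi_corpus(pubs)
}

record_to_list <- function(row) {
  rec <- list(id = row$pub_id)
  put <- function(rec, key, val) {
    if (length(val) == 1 && !is.na(val)) rec[[key]] <- val
    rec
  }
  rec <- put(rec, "title", row$title)
  rec <- put(rec, "abstract", row$abstract)
  rec <- put(rec, "methods", row$methods_text)
  rec <- put(rec, "pubYear", row$pub_year)
  if (!is.na(row$journal_year)) {
    rec$journalInfo <- list(yearOfPublication = row$journal_year)
  }
  rec <- put(rec, "firstPublicationDate", row$first_pub_date)
  rec <- put(rec, "electronicPublicationDate", row$electronic_pub_date)
  rec <- put(rec, "firstIndexDate", row$first_index_date)
  rec <- put(rec, "citedByCount", row$cited_by_count)
  ann <- row$annotations[[1]]
  if (!is.null(ann) && nrow(ann)) rec$annotations <- ann
  rec
}

#' Write a corpus back to the line-delimited record format
#'
#' Inverse of [read_corpus()]: absent fields are omitted from the JSON so a
#' write/read round trip reproduces all fields and absences exactly.
#'
#' @param corpus An `ldi_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  pubs <- corpus$publications
  lines <- vapply(seq_len(nrow(pubs)), function(i) {
    jsonlite::toJSON(record_to_list(pubs[i, ]), auto_unbox = TRUE,
                     digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# ---- annotation and entity tables ------------------------------------------

#' Attach a ChEBI annotation table to a corpus
#'
#' Reads a 4-column TSV (`pub_id`, `chebi_id`, `term`, `count`) in which each
#' row is a text-mined compound mention. Duplicate (`pub_id`, `chebi_id`)
#' rows have their counts summed, since per-sentence hits arrive as separate
#' rows. Rows referencing unknown publications are collected in
#' `corpus$orphans` and reported, never dropped silently.
#'
#' @param path Path to the annotation TSV (with header).
#' @param corpus The `ldi_corpus` to annotate.
#' @return The corpus with annotations attached.
#' @export
read_annotations <- function(path, corpus) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("pub_id", "chebi_id", "term", "count")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  ann$count <- as.integer(ann$count)
  if (any(is.na(ann$count) | ann$count <= 0)) {
    stop("annotation counts must be positive integers", call. = FALSE)
  }
  bad <- !grepl("^CHEBI:[0-9]+$", ann$chebi_id)
  if (any(bad)) {
    stop("malformed ChEBI identifier: ", ann$chebi_id[which(bad)[1]],
         call. = FALSE)
  }
  known <- ann$pub_id %in% corpus$publications$pub_id
  orphans <- as_tibble(ann[!known, need])
  if (nrow(orphans)) {
    message(nrow(orphans), " annotation row(s) reference unknown pub_id(s): ",
            paste(utils::head(unique(orphans$pub_id), 5), collapse = ", "))
  }
  attached <- dplyr::summarise(
    dplyr::group_by(as_tibble(ann[known, ]), .data$pub_id, .data$chebi_id),
    term = .data$term[1], count = sum(.data$count), .groups = "drop"
  )
  pubs <- corpus$publications
  split_ann <- split(attached[c("chebi_id", "term", "count")], attached$pub_id)
  idx <- match(names(split_ann), pubs$pub_id)
  for (k in seq_along(idx)) {
    old <- pubs$annotations[[idx[k]]]
    merged <- dplyr::summarise(
      dplyr::group_by(dplyr::bind_rows(old, as_tibble(split_ann[[k]])),
                      .data$chebi_id),
      term = .data$term[1], count = sum(.data$count), .groups = "drop"
    )
    pubs$annotations[[idx[k]]] <- merged
  }
  out <- ldi_corpus(pubs, corpus$entities, orphans)
  out
}

#' Read a chemical-entity table
#'
#' TSV columns: `chebi_id`, `name`, `formula`, `smiles`, `roles`
#' (semicolon-separated role labels, e.g. "MALDI matrix material"), and
#' optional `mw` (Da) and `logp`. A non-empty formula that does not parse as
#' element/count pairs triggers a warning; the entity is still loaded, with
#' the molecular weight unavailable unless given explicitly.
#'
#' @param path Path to the entity TSV (with header).
#' @return Tibble keyed by `chebi_id` with a `roles` list-column.
#' @export
read_entities <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!nrow(raw)) return(empty_entities())
  need <- c("chebi_id", "name", "formula", "smiles", "roles")
  if (!all(need %in% names(raw))) {
    stop("entity table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  num_or_na <- function(x) {
    if (is.null(x)) rep(NA_real_, nrow(raw)) else
      suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  }
  ent <- tibble(
    chebi_id = raw$chebi_id,
    name = raw$name,
    formula = ifelse(nzchar(raw$formula), raw$formula, NA_character_),
    smiles = ifelse(nzchar(raw$smiles), raw$smiles, NA_character_),
    roles = lapply(strsplit(raw$roles, ";", fixed = TRUE),
                   function(r) unique(trimws(r[nzchar(trimws(r))]))),
    mw = num_or_na(raw$mw),
    logp = num_or_na(raw$logp)
  )
  parse_ok <- vapply(ent$formula, function(f) {
    if (is.na(f)) return(TRUE)
    !inherits(try(parse_formula(f), silent = TRUE), "try-error")
  }, logical(1))
  if (any(!parse_ok)) {
    warning("unparseable formula for ",
            paste(ent$chebi_id[!parse_ok], collapse = ", "),
            "; molecular weight unavailable unless given explicitly",
            call. = FALSE)
  }
  if (any(!is.na(ent$mw) & ent$mw <= 0)) {
    stop("molecular weights must be positive", call. = FALSE)
  }
  ent
}

#' Write a chemical-entity table
#' @param entities Entity tibble as returned by [read_entities()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_entities <- function(entities, path) {
  out <- data.frame(
    chebi_id = entities$chebi_id,
    name = entities$name,
    formula = ifelse(is.na(entities$formula), "", entities$formula),
    smiles = ifelse(is.na(entities$smiles), "", entities$smiles),
    roles = vapply(entities$roles, paste, character(1), collapse = ";"),
    mw = ifelse(is.na(entities$mw), "", format(entities$mw, digits = 10)),
    logp = ifelse(is.na(entities$logp), "", format(entities$logp, digits = 10)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
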