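# End-to-end orchestration: simulate or load a corpus, run the technique
# query, build the enrichment table, export the VOSviewer file triplet and
# the property landscape, and record a machine-readable run manifest. The
# manifest contains inputs, settings, package version and seed -- but no
# timestamps, so a rerun with the same inputs is byte-identical.

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or a YAML file with the same
#' structure): either `corpus` (path to a JSONL record file, with optional
#' `annotations` and `entities` paths) or `simulate` (a list of
#' [generator_config()] arguments); `technique` (shorthand from the shipped
#' query set, or a query string); optional `substances` /
#' `nonmatrix_substances` TSV paths; `reference_year`; `weighting`;
#' `out_dir`; `seed`. Validation errors are signalled with class
#' `lditrends_validation_error` before any computation.
#'
#' @param config Named list or YAML path.
#' @return The normalized configuration list, invisibly classed.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      fail_validation("config file does not exist: ", config)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) fail_validation("config must be a list or YAML path")
  if (is.null(config$out_dir)) fail_validation("config needs an out_dir")
  if (is.null(config$corpus) && is.null(config$simulate)) {
    fail_validation("config needs either a corpus path or a simulate block")
  }
  for (key in c("corpus", "annotations", "entities", "substances",
                "nonmatrix_substances")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      fail_validation("configured ", key, " file does not exist: ", p)
    }
  }
  config$technique <- config$technique %||% "MALDI"
  config$reference_year <- as.integer(config$reference_year %||% 2023L)
  config$weighting <- config$weighting %||% "paper_chebi_pairs"
  config$seed <- as.integer(config$seed %||% 1L)
  config$vos_base_n <- config$vos_base_n %||% NULL
  config$vos_base_threshold <- as.integer(config$vos_base_threshold %||% 10L)
  invisible(config)
}

fail_validation <- function(...) {
  stop(structure(class = c("lditrends_validation_error", "error",
                           "condition"),
                 list(message = paste0(...), call = NULL)))
}

resolve_technique_query <- function(technique) {
  known <- technique_queries()
  if (technique %in% names(known)) {
    return(known[[technique]])
  }
  parse_query(technique)
}

load_substance_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  tibble(
    name = raw$name,
    synonyms = lapply(strsplit(raw$synonyms %||%
                                 rep("", nrow(raw)), ";", fixed = TRUE),
                      function(s) s[nzchar(trimws(s))])
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a corpus, evaluate the technique query, compute the
#' substance co-occurrence/enrichment table against the non-matrix
#' background, write the VOSviewer corpus/scores/thesaurus triplet, build
#' the molecular-property landscape, and write a run manifest. Outputs are
#' deterministic for fixed inputs and seed.
#'
#' @param config Run configuration list or YAML path; see
#'   [validate_run_config()].
#' @param quiet Suppress progress messages.
#' @return The output directory, invisibly. Files written:
#'   `enrichment.tsv`, `background.tsv`, `vos_corpus.txt`,
#'   `vos_scores.txt`, `vos_thesaurus.txt`, `landscape.tsv`,
#'   `landscape.json`, `manifest.json`.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  config <- validate_run_config(config)
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$corpus)) {
    say("reading corpus from ", config$corpus)
    corpus <- read_corpus(config$corpus)
    if (!is.null(config$entities)) {
      corpus$entities <- read_entities(config$entities)
      corpus <- ldi_corpus(corpus$publications, corpus$entities)
    }
    if (!is.null(config$annotations)) {
      corpus <- read_annotations(config$annotations, corpus)
    }
  } else {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    say("simulating corpus (n = ", sim_args$n_publications %||% 1000,
        ", seed = ", sim_args$seed, ")")
    gen <- generate_corpus(do.call(generator_config, sim_args))
    corpus <- gen$corpus
  }

  technique <- resolve_technique_query(config$technique)
  n_match <- count_matches(corpus, technique)
  say(n_match, " of ", n_publications(corpus),
      " publications match technique '", config$technique, "'")

  matrices <- if (!is.null(config$substances)) {
    load_substance_table(config$substances)
  } else {
    ldi_substances("matrix")
  }
  nonmatrix <- if (!is.null(config$nonmatrix_substances)) {
    load_substance_table(config$nonmatrix_substances)
  } else {
    ldi_substances("nonmatrix")
  }

  say("building co-occurrence table (", nrow(matrices), " substances)")
  tab <- build_cooccurrence_table(corpus, matrices, technique)
  bg <- tryCatch(background_rate(corpus, nonmatrix, technique),
                 error = function(e) NULL)
  bg_ok <- !is.null(bg) && bg$mean_percent > 0
  if (bg_ok) {
    tab <- flag_enriched(tab, bg)
  } else {
    say("background rate unavailable; enrichment flags skipped")
    tab$enriched <- NA
  }
  enr_out <- round_ratio_cols(tab, digits = 3)
  utils::write.table(enr_out, file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(bg)) {
    utils::write.table(
      data.frame(substance = bg$fractions$substance,
                 total = bg$fractions$total,
                 with_technique = bg$fractions$with_technique,
                 percent = round(bg$fractions$percent, 3)),
      file.path(config$out_dir, "background.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("writing VOSviewer files")
  records <- score_records(corpus, reference_year = config$reference_year)
  write_scores_file(records, file.path(config$out_dir, "vos_scores.txt"))
  write_corpus_file(corpus, file.path(config$out_dir, "vos_corpus.txt"),
                    records)
  write_thesaurus(path = file.path(config$out_dir, "vos_thesaurus.txt"))

  say("building property landscape")
  landscape <- build_landscape(corpus, technique = technique,
                               weighting = config$weighting,
                               drop_matrix_role = TRUE)
  write_landscape(landscape, file.path(config$out_dir, "landscape.tsv"))

  manifest <- list(
    package = "lditrends",
    version = as.character(utils::packageVersion("lditrends")),
    seed = config$seed,
    inputs = list(
      corpus = config$corpus %||% "simulated",
      simulate = config$simulate,
      substances = config$substances %||% "builtin",
      nonmatrix_substances = config$nonmatrix_substances %||% "builtin"
    ),
    settings = list(
      technique = config$technique,
      reference_year = config$reference_year,
      weighting = config$weighting,
      vos_base_threshold = config$vos_base_threshold,
      vos_base_n = config$vos_base_n
    ),
    results = list(
      n_publications = n_publications(corpus),
      n_matching_technique = n_match,
      vos_min_occurrences = normalized_min_occurrences(
        n_match, config$vos_base_n %||% n_match,
        config$vos_base_threshold),
      background_mean_percent = if (!is.null(bg)) bg$mean_percent else NULL,
      background_sd_percent = if (!is.null(bg)) bg$sd_percent else NULL,
      n_enriched = if (bg_ok) sum(tab$enriched) else NULL,
      landscape_totals = landscape$totals
    ),
    outputs = c("enrichment.tsv", if (!is.null(bg)) "background.tsv",
                "vos_scores.txt", "vos_corpus.txt", "vos_thesaurus.txt",
                "landscape.tsv", "landscape.json")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("done: ", config$out_dir)
  invisible(config$out_dir)
}

round_ratio_cols <- function(tab, digits = 3) {
  for (col in c("technique_fraction", "sm_pp", "sm_op")) {
    tab[[col]] <- round(tab[[col]], digits)
  }
  tab
}
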