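# Seeded synthetic corpora with exact ground truth.
#
# Each publication gets latent labels -- technique(s), analyte contexts,
# substance mentions -- drawn from a conditional model, and the
# corresponding query phrases are injected verbatim into the title,
# abstract or methods text, padded with filler words drawn from a fixed
# vocabulary that shares no token with any query phrase. Injection is
# therefore lossless: evaluating the query engine on the generated text
# reproduces the latent labels exactly, and the realized count table is an
# exact oracle for the enrichment pipeline.
#
# Non-matrix chemicals are calibrated so that the fraction of their
# publications co-occurring with the technique has expectation equal to
# `background_rate` (about 1%): with technique prevalence pi and target
# background b, the mention probability given the technique is
# p0 * b(1-pi) / ((1-b) pi) against p0 without it.

FILLER_VOCAB <- c(
  "the", "a", "of", "in", "we", "this", "study", "results", "using",
  "approach", "data", "observed", "measured", "conditions", "experiments",
  "values", "further", "novel", "reported", "samples", "obtained",
  "described", "procedure", "buffer", "instrument", "signal", "spectra",
  "acquisition", "calibration", "replicates", "temperature", "overnight",
  "aliquot", "mixture", "solvent", "gradient", "elution", "workflow",
  "and", "were", "was", "for", "with", "from", "after", "before"
)

CONTEXT_VARIANTS <- list(
  sm = c("small molecule", "small molecules"),
  pp = c("peptide", "peptides", "protein", "proteins"),
  op = c("oligomer", "oligomers", "polymer", "polymers")
)

#' Define an analyte class for the synthetic generator
#'
#' An analyte class is a pool of synthetic ChEBI entities whose molecular
#' weights follow a log-normal distribution and whose logP values follow a
#' normal distribution, annotated in publications at a Poisson rate.
#'
#' @param name Class label.
#' @param n_entities Number of distinct entities in the pool.
#' @param mw_meanlog,mw_sdlog Log-normal parameters for molecular weight
#'   (Da); `mw_sdlog` must be positive.
#' @param logp_mean,logp_sd Normal parameters for logP; `logp_sd` positive.
#' @param mean_entities_per_pub Poisson mean of distinct entities from this
#'   class annotated per publication.
#' @return A list describing the class.
#' @export
analyte_class <- function(name, n_entities, mw_meanlog, mw_sdlog,
                          logp_mean, logp_sd, mean_entities_per_pub) {
  stopifnot(n_entities >= 1, mw_sdlog > 0, logp_sd > 0,
            mean_entities_per_pub >= 0)
  list(name = name, n_entities = as.integer(n_entities),
       mw_meanlog = mw_meanlog, mw_sdlog = mw_sdlog,
       logp_mean = logp_mean, logp_sd = logp_sd,
       mean_entities_per_pub = mean_entities_per_pub)
}

default_analyte_classes <- function() {
  list(
    analyte_class("metabolite", 120, log(200), 0.5, 0.5, 1.0, 2.0),
    analyte_class("oligosaccharide", 40, log(450), 0.35, -2.3, 0.25, 0.6),
    analyte_class("lipid", 40, log(700), 0.3, 7.0, 1.5, 0.4)
  )
}

default_synthetic_substances <- function() {
  subs <- ldi_substances("all")
  # names containing context-query tokens ("polymer") would break the exact
  # text-injection ground truth, so they are left out of the generator
  drop <- grepl("polymer|oligomer|peptide|protein|molecule",
                paste(subs$name,
                      vapply(subs$synonyms, paste, "", collapse = " ")),
                ignore.case = TRUE)
  subs <- subs[!drop, ]
  is_matrix <- subs$group == "matrix"
  tibble(
    name = subs$name,
    synonyms = subs$synonyms,
    kind = subs$group,
    technique = "MALDI",
    # matrices: strong conditional co-occurrence with their technique; the
    # off-technique rate spans two orders of magnitude so that, as in the
    # real literature, some matrices nearly always co-occur with the
    # technique while others have substantial other uses
    p_given_tech = ifelse(is_matrix,
                          round(stats::runif(nrow(subs), 0.3, 0.8), 2), NA),
    p_base = ifelse(is_matrix,
                    signif(10^stats::runif(nrow(subs), -2.7, -0.7), 2),
                    round(stats::runif(nrow(subs), 0.05, 0.15), 2))
  )
}

#' Synthetic-corpus generator configuration
#'
#' Collects every tunable of the generative model: corpus size, latent
#' technique prevalences and phrases, the substance mention model (matrix
#' substances with conditional mention probabilities, non-matrix chemicals
#' calibrated to a ~1% background technique co-occurrence), analyte-context
#' probabilities, analyte classes with molecular-property distributions,
#' the publication-year missingness cascade, and an age-proportional
#' negative-binomial citation model.
#'
#' `default_synthetic_substances()` draws per-substance probabilities, so
#' the configuration itself is built under the seed to stay reproducible.
#'
#' @param n_publications Corpus size (>= 1).
#' @param technique_prevalence Named probabilities of each latent technique.
#' @param technique_phrases Named list of injectable phrase synonyms per
#'   technique.
#' @param guard_phrases Phrases satisfying the mass-spectrometry guard.
#' @param guard_rate Probability a publication's methods section mentions
#'   mass spectrometry at all.
#' @param substances Substance tibble (`name`, `synonyms`, `kind`,
#'   `technique`, `p_given_tech`, `p_base`); `NULL` for the built-in list.
#' @param background_rate Target P(technique | non-matrix chemical
#'   mentioned), default 0.01.
#' @param context_given_technique,context_base_rate Named (`sm`, `pp`,
#'   `op`) probabilities of each analyte context with / without the
#'   technique.
#' @param analyte_classes List of [analyte_class()] definitions.
#' @param year_range Inclusive year range of publications.
#' @param year_provenance_probs Named categorical distribution over which
#'   year field resolves first (`pubYear`, `journal_year`,
#'   `first_pub_date`, `electronic_pub_date`, `first_index_date`,
#'   `imputed_median`); `imputed_median` is the all-fields-absent case.
#' @param citations_per_year Expected citations accrued per year of age.
#' @param citation_dispersion Negative-binomial size parameter.
#' @param citation_missing_rate Probability the citation field is absent.
#' @param reference_year Year "today" for citation ages.
#' @param seed Integer seed; fixed seed gives byte-identical corpora.
#' @return An object of class `ldi_generator_config`.
#' @export
generator_config <- function(
    n_publications = 1000,
    technique_prevalence = c(MALDI = 0.25, SALDI = 0.05),
    technique_phrases = list(
      MALDI = c("MALDI", "matrix-assisted laser desorption/ionization"),
      SALDI = c("SALDI", "surface assisted")
    ),
    guard_phrases = c("mass spectrometry", "MS"),
    guard_rate = 1.0,
    substances = NULL,
    background_rate = 0.01,
    context_given_technique = c(sm = 0.15, pp = 0.45, op = 0.15),
    context_base_rate = c(sm = 0.03, pp = 0.08, op = 0.03),
    analyte_classes = default_analyte_classes(),
    year_range = c(1985, 2023),
    year_provenance_probs = c(pubYear = 0.78, journal_year = 0.05,
                              first_pub_date = 0.06,
                              electronic_pub_date = 0.04,
                              first_index_date = 0.04,
                              imputed_median = 0.03),
    citations_per_year = 2.0,
    citation_dispersion = 1.2,
    citation_missing_rate = 0.03,
    reference_year = 2023L,
    seed = 1L) {
  if (is.null(substances)) {
    substances <- with_seed(seed, default_synthetic_substances())
  }
  cfg <- structure(
    list(
      n_publications = as.integer(n_publications),
      technique_prevalence = technique_prevalence,
      technique_phrases = technique_phrases,
      guard_phrases = guard_phrases,
      guard_rate = guard_rate,
      substances = substances,
      background_rate = background_rate,
      context_given_technique = context_given_technique,
      context_base_rate = context_base_rate,
      analyte_classes = analyte_classes,
      year_range = as.integer(year_range),
      year_provenance_probs = year_provenance_probs,
      citations_per_year = citations_per_year,
      citation_dispersion = citation_dispersion,
      citation_missing_rate = citation_missing_rate,
      reference_year = as.integer(reference_year),
      seed = as.integer(seed)
    ),
    class = "ldi_generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$technique_prevalence, cfg$guard_rate, cfg$background_rate,
             cfg$context_given_technique, cfg$context_base_rate,
             cfg$citation_missing_rate, cfg$year_provenance_probs,
             cfg$substances$p_base,
             cfg$substances$p_given_tech[!is.na(cfg$substances$p_given_tech)])
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_publications < 1) {
    stop("n_publications must be at least 1", call. = FALSE)
  }
  if (abs(sum(cfg$year_provenance_probs) - 1) > 1e-8) {
    stop("year_provenance_probs must sum to 1", call. = FALSE)
  }
  if (!setequal(names(cfg$year_provenance_probs), YEAR_PROVENANCE)) {
    stop("year_provenance_probs must be named by the five year fields plus ",
         "imputed_median", call. = FALSE)
  }
  if (!all(names(cfg$technique_prevalence) %in%
           names(cfg$technique_phrases))) {
    stop("every technique needs phrases", call. = FALSE)
  }
  if (!all(cfg$substances$technique %in% names(cfg$technique_prevalence))) {
    stop("substances reference unknown techniques", call. = FALSE)
  }
  assert_phrase_safety(cfg)
  invisible(cfg)
}

phrase_tokens <- function(phrases) {
  unique(unlist(strsplit(trimws(gsub("[^a-z0-9]+", " ",
                                     tolower(phrases))), " ")))
}

assert_phrase_safety <- function(cfg) {
  all_phrases <- c(unlist(cfg$technique_phrases), cfg$guard_phrases,
                   unlist(CONTEXT_VARIANTS),
                   cfg$substances$name, unlist(cfg$substances$synonyms))
  clash <- intersect(FILLER_VOCAB, phrase_tokens(all_phrases))
  if (length(clash)) {
    stop("filler vocabulary collides with query phrase token(s): ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  # no substance phrase may occur inside another substance's phrases
  norm <- function(p) paste0(" ", trimws(gsub("[^a-z0-9]+", " ",
                                              tolower(p))), " ")
  subs <- cfg$substances
  phr <- lapply(seq_len(nrow(subs)),
                function(i) norm(c(subs$name[i], subs$synonyms[[i]])))
  for (i in seq_along(phr)) {
    for (j in seq_along(phr)) {
      if (i == j) next
      hit <- outer(phr[[j]], phr[[i]],
                   Vectorize(function(a, b) grepl(a, b, fixed = TRUE)))
      if (any(hit)) {
        stop("substance phrase collision between '", subs$name[i], "' and '",
             subs$name[j], "'", call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

filler <- function(n, k) {
  if (k == 0) return(rep("", n))
  words <- matrix(sample(FILLER_VOCAB, n * k, replace = TRUE), nrow = n)
  do.call(paste, as.data.frame(words, stringsAsFactors = FALSE))
}

pick_phrases <- function(flags, variants) {
  # for each row of the logical matrix `flags`, pick one variant phrase per
  # fired column and join with a filler separator
  n <- nrow(flags)
  out <- rep("", n)
  for (j in seq_len(ncol(flags))) {
    v <- variants[[j]]
    chosen <- v[sample.int(length(v), n, replace = TRUE)]
    out <- ifelse(flags[, j], ifelse(nzchar(out),
                                     paste(out, "and", chosen), chosen), out)
  }
  out
}

#' Generate a synthetic corpus with ground truth
#'
#' Deterministic for a fixed seed. Returns both the corpus (publications
#' with injected phrases, annotations and entity table) and the realized
#' ground truth (latent labels, count table, property moments, year
#' provenance, citation model) against which pipeline output can be
#' compared exactly.
#'
#' @param config An [generator_config()].
#' @return List with elements `corpus` (an `ldi_corpus`) and `truth`
#'   (an `ldi_ground_truth`).
#' @export
generate_corpus <- function(config = generator_config()) {
  validate_generator_config(config)
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  n <- cfg$n_publications
  tech_names <- names(cfg$technique_prevalence)
  pub_id <- sprintf("SYN%07d", seq_len(n))

  # latent labels ------------------------------------------------------------
  tech <- vapply(tech_names, function(t) {
    stats::runif(n) < cfg$technique_prevalence[[t]]
  }, logical(n))
  if (n == 1) tech <- matrix(tech, nrow = 1, dimnames = list(NULL, tech_names))
  guard <- stats::runif(n) < cfg$guard_rate
  tech_eff <- tech & guard  # a technique query can only fire with its guard

  subs <- cfg$substances
  pi_by_tech <- cfg$technique_prevalence
  b <- cfg$background_rate
  mention <- matrix(FALSE, n, nrow(subs),
                    dimnames = list(NULL, subs$name))
  p_tech_used <- numeric(nrow(subs))
  for (i in seq_len(nrow(subs))) {
    t <- subs$technique[i]
    p0 <- subs$p_base[i]
    p1 <- if (!is.na(subs$p_given_tech[i])) {
      subs$p_given_tech[i]
    } else {
      # calibrate so P(technique | mention) = background_rate
      pi_t <- pi_by_tech[[t]] * cfg$guard_rate
      min(1, p0 * b * (1 - pi_t) / ((1 - b) * pi_t))
    }
    p_tech_used[i] <- p1
    p <- ifelse(tech_eff[, t], p1, p0)
    mention[, i] <- stats::runif(n) < p
  }

  ctx_names <- names(CONTEXT_VARIANTS)
  ctx <- matrix(FALSE, n, length(ctx_names),
                dimnames = list(NULL, ctx_names))
  anchor <- tech_eff[, 1]  # contexts co-vary with the first (main) technique
  for (c in ctx_names) {
    p <- ifelse(anchor, cfg$context_given_technique[[c]],
                cfg$context_base_rate[[c]])
    ctx[, c] <- stats::runif(n) < p
  }

  # text assembly ------------------------------------------------------------
  tech_txt <- pick_phrases(tech, cfg$technique_phrases[tech_names])
  guard_txt <- ifelse(guard,
                      cfg$guard_phrases[sample.int(length(cfg$guard_phrases),
                                                   n, replace = TRUE)], "")
  subs_variants <- lapply(seq_len(nrow(subs)), function(i) {
    unique(c(subs$name[i], subs$synonyms[[i]]))
  })
  subs_txt <- pick_phrases(mention, subs_variants)
  ctx_txt <- pick_phrases(ctx, CONTEXT_VARIANTS)

  join_nz <- function(...) {
    parts <- list(...)
    out <- rep("", length(parts[[1]]))
    for (p in parts) {
      out <- ifelse(nzchar(p), ifelse(nzchar(out), paste(out, p), p), out)
    }
    out
  }
  title <- filler(n, 4)
  abstract <- join_nz(filler(n, 6), subs_txt, filler(n, 3), ctx_txt,
                      filler(n, 4))
  methods_text <- join_nz(filler(n, 4), guard_txt, filler(n, 2), tech_txt,
                          filler(n, 3))

  # years and citations -------------------------------------------------------
  prov_levels <- names(cfg$year_provenance_probs)
  provenance <- prov_levels[sample.int(length(prov_levels), n, replace = TRUE,
                                       prob = cfg$year_provenance_probs)]
  year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE)
  date_of <- function(y) sprintf("%04d-%02d-%02d", y,
                                 sample(1:12, length(y), TRUE),
                                 sample(1:28, length(y), TRUE))
  order_fields <- YEAR_PROVENANCE[1:5]
  fields <- list(pub_year = rep(NA_integer_, n),
                 journal_year = rep(NA_integer_, n),
                 first_pub_date = rep(NA_character_, n),
                 electronic_pub_date = rep(NA_character_, n),
                 first_index_date = rep(NA_character_, n))
  set_field <- function(fields, fname, idx) {
    if (!length(idx)) return(fields)
    if (fname %in% c("pub_year", "journal_year")) {
      fields[[fname]][idx] <- year[idx]
    } else {
      fields[[fname]][idx] <- date_of(year[idx])
    }
    fields
  }
  fname_of <- c(pubYear = "pub_year", journal_year = "journal_year",
                first_pub_date = "first_pub_date",
                electronic_pub_date = "electronic_pub_date",
                first_index_date = "first_index_date")
  for (k in seq_along(order_fields)) {
    lab <- order_fields[k]
    fields <- set_field(fields, fname_of[[lab]], which(provenance == lab))
    # later-order fields may be present too; earlier ones must stay absent
    if (k < 5) {
      for (k2 in (k + 1):5) {
        later <- which(provenance == lab & stats::runif(n) < 0.5)
        fields <- set_field(fields, fname_of[[order_fields[k2]]], later)
      }
    }
  }
  resolved_year <- ifelse(provenance == "imputed_median", 2006L, year)
  age <- pmax(cfg$reference_year - resolved_year, 1L)
  citations <- stats::rnbinom(n, size = cfg$citation_dispersion,
                              mu = cfg$citations_per_year * age)
  cite_missing <- stats::runif(n) < cfg$citation_missing_rate
  cited_by_count <- ifelse(cite_missing, NA_integer_, as.integer(citations))

  # entities and annotations ---------------------------------------------------
  ents <- synth_entities(cfg)
  entities <- ents$entities
  pairs <- synth_annotations(cfg, n, pub_id, mention, ents)

  ann_split <- split(pairs[c("chebi_id", "term", "count")], pairs$pub_id)
  annotations <- replicate(n, empty_annotations(), simplify = FALSE)
  idx <- match(names(ann_split), pub_id)
  for (k in seq_along(idx)) {
    annotations[[idx[k]]] <- as_tibble(ann_split[[k]])
  }

  pubs <- tibble(
    pub_id = pub_id, title = title, abstract = abstract,
    methods_text = methods_text,
    pub_year = fields$pub_year, journal_year = fields$journal_year,
    first_pub_date = fields$first_pub_date,
    electronic_pub_date = fields$electronic_pub_date,
    first_index_date = fields$first_index_date,
    cited_by_count = cited_by_count,
    annotations = annotations
  )
  corpus <- ldi_corpus(pubs, entities)

  truth <- structure(
    list(
      pub_id = pub_id,
      technique_flags = tech_eff,
      technique_label = tech,
      guard = guard,
      context_flags = ctx,
      mention_flags = mention,
      substances = subs,
      p_mention_given_technique = stats::setNames(p_tech_used, subs$name),
      year = tibble(pub_id = pub_id, provenance = provenance,
                    resolved_year = as.integer(resolved_year),
                    age = as.integer(age)),
      citations = tibble(pub_id = pub_id,
                         citations = as.integer(citations),
                         missing = cite_missing),
      annotation_pairs = pairs,
      entities = entities,
      config = cfg
    ),
    class = "ldi_ground_truth"
  )
  list(corpus = corpus, truth = truth)
}

synth_entities <- function(cfg) {
  class_rows <- lapply(seq_along(cfg$analyte_classes), function(ci) {
    cl <- cfg$analyte_classes[[ci]]
    k <- cl$n_entities
    tibble(
      chebi_id = sprintf("CHEBI:9%02d%03d", ci, seq_len(k)),
      name = sprintf("synthetic-%s-%03d", cl$name, seq_len(k)),
      formula = NA_character_,
      smiles = NA_character_,
      roles = replicate(k, character(0), simplify = FALSE),
      mw = stats::rlnorm(k, cl$mw_meanlog, cl$mw_sdlog),
      logp = stats::rnorm(k, cl$logp_mean, cl$logp_sd),
      class = cl$name
    )
  })
  subs <- cfg$substances
  matrix_rows <- NULL
  is_m <- subs$kind == "matrix"
  if (any(is_m)) {
    k <- sum(is_m)
    matrix_rows <- tibble(
      chebi_id = sprintf("CHEBI:800%03d", seq_len(k)),
      name = subs$name[is_m],
      formula = NA_character_,
      smiles = NA_character_,
      roles = replicate(k, "MALDI matrix material", simplify = FALSE),
      mw = stats::rlnorm(k, log(220), 0.25),
      logp = stats::rnorm(k, 2, 0.7),
      class = "matrix"
    )
  }
  all_rows <- dplyr::bind_rows(c(class_rows, list(matrix_rows)))
  list(entities = all_rows[, c("chebi_id", "name", "formula", "smiles",
                               "roles", "mw", "logp")],
       class_of = stats::setNames(all_rows$class, all_rows$chebi_id),
       matrix_chebi = if (is.null(matrix_rows)) character(0) else
         stats::setNames(matrix_rows$chebi_id, matrix_rows$name))
}

synth_annotations <- function(cfg, n, pub_id, mention, ents) {
  pieces <- list()
  offset <- 0L
  for (ci in seq_along(cfg$analyte_classes)) {
    cl <- cfg$analyte_classes[[ci]]
    pool <- ents$entities$chebi_id[ents$class_of == cl$name]
    k_per_pub <- pmin(stats::rpois(n, cl$mean_entities_per_pub), length(pool))
    tot <- sum(k_per_pub)
    if (!tot) next
    which_pub <- rep.int(seq_len(n), k_per_pub)
    chosen <- unlist(lapply(k_per_pub[k_per_pub > 0], function(k) {
      pool[sample.int(length(pool), k)]
    }))
    pieces[[length(pieces) + 1L]] <- tibble(
      pub_id = pub_id[which_pub],
      chebi_id = chosen,
      term = ents$entities$name[match(chosen, ents$entities$chebi_id)],
      count = 1L + stats::rpois(tot, 0.6),
      class = cl$name
    )
  }
  # matrix substances are picked up by the entity recognizer wherever the
  # substance is mentioned in the text
  for (nm in names(ents$matrix_chebi)) {
    hit <- which(mention[, nm])
    if (!length(hit)) next
    pieces[[length(pieces) + 1L]] <- tibble(
      pub_id = pub_id[hit],
      chebi_id = ents$matrix_chebi[[nm]],
      term = nm,
      count = 1L + stats::rpois(length(hit), 0.3),
      class = "matrix"
    )
  }
  if (!length(pieces)) {
    return(tibble(pub_id = character(), chebi_id = character(),
                  term = character(), count = integer(),
                  class = character()))
  }
  out <- dplyr::bind_rows(pieces)
  out[order(match(out$pub_id, pub_id), out$chebi_id), ]
}

#' Realized co-occurrence counts from ground truth
#'
#' The exact count table implied by the generator's latent labels: for each
#' substance, the number of publications mentioning it, co-occurring with
#' the technique, and additionally matching each analyte context. This is
#' the oracle against which [build_cooccurrence_table()] output is compared
#' -- on synthetic corpora the two must agree exactly.
#'
#' @param truth An `ldi_ground_truth` from [generate_corpus()].
#' @param technique Technique name (default the first configured one).
#' @return Tibble with the same columns and ordering as
#'   [build_cooccurrence_table()].
#' @export
truth_summary <- function(truth, technique = NULL) {
  subs <- truth$substances
  if (!nrow(subs) || !length(truth$pub_id)) {
    out <- tibble(substance = character(), total = integer(),
                  with_technique = integer(), with_sm = integer(),
                  with_pp = integer(), with_op = integer(),
                  technique_fraction = numeric(), sm_pp = numeric(),
                  sm_op = numeric())
    return(out)
  }
  technique <- technique %||% colnames(truth$technique_flags)[1]
  t <- truth$technique_flags[, technique]
  rows <- lapply(seq_len(nrow(subs)), function(i) {
    m <- truth$mention_flags[, subs$name[i]]
    tibble(
      substance = subs$name[i],
      total = sum(m),
      with_technique = sum(m & t),
      with_sm = sum(m & t & truth$context_flags[, "sm"]),
      with_pp = sum(m & t & truth$context_flags[, "pp"]),
      with_op = sum(m & t & truth$context_flags[, "op"])
    )
  })
  out <- dplyr::bind_rows(rows)
  out$technique_fraction <- context_ratio(out$with_technique, out$total)
  out$sm_pp <- context_ratio(out$with_sm, out$with_pp)
  out$sm_op <- context_ratio(out$with_sm, out$with_op)
  out[order(-out$with_technique, out$substance), ]
}

#' @export
print.ldi_ground_truth <- function(x, ...) {
  cat("<ldi_ground_truth> ", length(x$pub_id), " publications, ",
      nrow(x$substances), " substances, ",
      nrow(x$annotation_pairs), " annotation pairs\n", sep = "")
  invisible(x)
}
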