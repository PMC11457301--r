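# Molecular-property landscapes: text-mined compound mentions placed in
# logP x molecular-weight space. The x axis is logP and the y axis
# molecular weight, so a compound family with a shared logP and spread-out
# masses (e.g. small oligosaccharides) appears as a vertical line.
#
# Property sources, in order of precedence: an explicit mw/logp field on
# the entity (so published property tables can be ingested unchanged), a
# value computed from the formula (mw) or SMILES (logP), otherwise the
# entity is excluded with a warning and counted.

#' Property points for annotated entities
#'
#' One point per distinct entity annotated in the (optionally
#' technique-sliced) corpus: its molecular weight and logP, the number of
#' publications annotating it, and the total number of named-entity
#' recognitions. Entities for which neither an explicit nor a computable
#' property value exists are excluded with a warning.
#'
#' @param corpus An `ldi_corpus` with entities.
#' @param technique Optional `ldi_query` (or string); when given, only
#'   publications matching it contribute annotations.
#' @param entities Entity table; defaults to `corpus$entities`.
#' @return Tibble with `chebi_id`, `mw`, `logp`, `n_papers`,
#'   `n_recognitions`.
#' @export
property_points <- function(corpus, technique = NULL,
                            entities = corpus$entities) {
  pubs <- corpus$publications
  keep <- rep(TRUE, nrow(pubs))
  if (!is.null(technique)) {
    if (is.character(technique)) technique <- parse_query(technique)
    keep <- eval_query(corpus, technique)
  }
  flat <- dplyr::bind_rows(lapply(which(keep), function(i) {
    a <- pubs$annotations[[i]]
    if (!nrow(a)) return(NULL)
    tibble(chebi_id = a$chebi_id, count = a$count)
  }))
  if (!nrow(flat)) {
    return(tibble(chebi_id = character(), mw = numeric(), logp = numeric(),
                  n_papers = integer(), n_recognitions = integer()))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(flat, .data$chebi_id),
    n_papers = dplyr::n(), n_recognitions = sum(.data$count),
    .groups = "drop"
  )
  idx <- match(agg$chebi_id, entities$chebi_id)
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning("annotations reference ", sum(unknown),
            " entity id(s) missing from the entity table; excluded",
            call. = FALSE)
    agg <- agg[!unknown, ]
    idx <- idx[!unknown]
  }
  mw <- entities$mw[idx]
  need_mw <- is.na(mw)
  if (any(need_mw)) {
    mw[need_mw] <- vapply(entities$formula[idx[need_mw]], function(f) {
      if (is.na(f)) return(NA_real_)
      tryCatch(compute_mw(f), error = function(e) NA_real_)
    }, numeric(1))
  }
  logp <- entities$logp[idx]
  need_lp <- is.na(logp)
  if (any(need_lp)) {
    logp[need_lp] <- vapply(entities$smiles[idx[need_lp]], function(s) {
      if (is.na(s)) return(NA_real_)
      tryCatch(compute_logp(s), error = function(e) NA_real_)
    }, numeric(1))
  }
  drop <- is.na(mw) | is.na(logp) | mw <= 0
  if (any(drop)) {
    warning(sum(drop), " entity(ies) excluded from the landscape: no ",
            "molecular weight or logP available", call. = FALSE)
  }
  tibble(chebi_id = agg$chebi_id, mw = mw, logp = logp,
         n_papers = as.integer(agg$n_papers),
         n_recognitions = as.integer(agg$n_recognitions))[!drop, ]
}

#' Remove known matrix substances from a point set
#'
#' Compounds carrying the given ChEBI role (by default "MALDI matrix
#' material") are expected to co-appear with the ionization techniques for
#' instrumental rather than analytical reasons, and are removed before
#' visualization. The number removed is reported.
#'
#' @param points Property points from [property_points()].
#' @param entities Entity table with a `roles` list-column.
#' @param role Role label to remove.
#' @return Filtered points tibble.
#' @export
filter_matrix_role <- function(points, entities,
                               role = "MALDI matrix material") {
  has_role <- vapply(entities$roles, function(r) role %in% r, logical(1))
  bad_ids <- entities$chebi_id[has_role]
  drop <- points$chebi_id %in% bad_ids
  message("removed ", sum(drop), " matrix-role compound(s) of ",
          nrow(points))
  out <- points[!drop, ]
  if (nrow(points) && !nrow(out)) {
    warning("all points carried the matrix role; landscape is empty",
            call. = FALSE)
  }
  out
}

#' Default landscape bin edges
#'
#' logP from -10 to 15 in steps of 0.5 (x), molecular weight from 0 to
#' 1500 Da in steps of 25 (y): wide enough to cover typical text-mined
#' small-molecule corpora.
#'
#' @return List with `logp` and `mw` edge vectors.
#' @export
default_landscape_bins <- function() {
  list(logp = seq(-10, 15, by = 0.5), mw = seq(0, 1500, by = 25))
}

#' Build a 2D property landscape
#'
#' Bins property points on a logP (x) by molecular-weight (y) grid. Cell
#' weights are either the number of publication-entity pairs
#' (`"paper_chebi_pairs"`, default: each paper counts once per compound) or
#' the total number of named-entity recognitions (`"recognitions"`).
#' Out-of-range points are counted and reported, never silently clipped.
#'
#' @param corpus An `ldi_corpus`, or a precomputed points tibble.
#' @param technique Optional technique query selecting the corpus slice.
#' @param entities Entity table (defaults to `corpus$entities`).
#' @param bins List with `logp` and `mw` strictly increasing edge vectors.
#' @param weighting `"paper_chebi_pairs"` or `"recognitions"`.
#' @param drop_matrix_role Remove "MALDI matrix material" compounds first.
#' @return An `ldi_landscape`: bin edges, weight matrix, totals, and the
#'   out-of-range count.
#' @export
build_landscape <- function(corpus, technique = NULL,
                            entities = NULL,
                            bins = default_landscape_bins(),
                            weighting = c("paper_chebi_pairs",
                                          "recognitions"),
                            drop_matrix_role = FALSE) {
  weighting <- match.arg(weighting)
  n_annotated_pubs <- NA_integer_
  if (inherits(corpus, "ldi_corpus")) {
    entities <- entities %||% corpus$entities
    points <- property_points(corpus, technique, entities)
    keep <- if (is.null(technique)) rep(TRUE, n_publications(corpus)) else {
      q <- if (is.character(technique)) parse_query(technique) else technique
      eval_query(corpus, q)
    }
    n_annotated_pubs <- sum(vapply(corpus$publications$annotations[keep],
                                   nrow, 0L) > 0L)
  } else {
    points <- corpus
    if (is.null(entities) && drop_matrix_role) {
      stop("drop_matrix_role needs an entity table", call. = FALSE)
    }
  }
  if (drop_matrix_role) points <- filter_matrix_role(points, entities)
  xe <- bins$logp
  ye <- bins$mw
  if (is.unsorted(xe, strictly = TRUE) || is.unsorted(ye, strictly = TRUE)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  w <- if (weighting == "paper_chebi_pairs") points$n_papers else
    points$n_recognitions
  grid <- matrix(0, nrow = length(xe) - 1L, ncol = length(ye) - 1L)
  in_range <- rep(FALSE, nrow(points))
  if (nrow(points)) {
    xi <- findInterval(points$logp, xe, rightmost.closed = TRUE)
    yi <- findInterval(points$mw, ye, rightmost.closed = TRUE)
    in_range <- xi >= 1 & xi <= nrow(grid) & yi >= 1 & yi <= ncol(grid)
    for (k in which(in_range)) {
      grid[xi[k], yi[k]] <- grid[xi[k], yi[k]] + w[k]
    }
  }
  structure(
    list(
      logp_edges = xe, mw_edges = ye, weights = grid,
      weighting = weighting,
      totals = list(
        unique_chebis = nrow(points),
        papers_with_annotations = n_annotated_pubs,
        paper_chebi_pairs = sum(points$n_papers),
        recognitions = sum(points$n_recognitions)
      ),
      out_of_range = list(points = sum(!in_range),
                          weight = sum(w[!in_range])),
      points = points
    ),
    class = "ldi_landscape"
  )
}

#' @export
print.ldi_landscape <- function(x, ...) {
  cat("<ldi_landscape> ", x$totals$unique_chebis, " compounds, ",
      x$totals$paper_chebi_pairs, " paper-compound pairs, ",
      x$totals$recognitions, " recognitions; ",
      x$out_of_range$points, " point(s) out of range\n", sep = "")
  invisible(x)
}

#' Weighted property averages
#'
#' Mean molecular weight (Da) and mean logP over a point set, weighted by
#' publication-entity pairs or recognitions, reported to 2 decimals. With
#' `weighting = "unique"` every compound counts once.
#'
#' @param points Property points tibble.
#' @param weighting `"paper_chebi_pairs"`, `"recognitions"`, or `"unique"`.
#' @return Named numeric vector `c(mean_mw, mean_logp)`.
#' @export
property_summary <- function(points,
                             weighting = c("paper_chebi_pairs",
                                           "recognitions", "unique")) {
  weighting <- match.arg(weighting)
  if (!nrow(points)) {
    return(c(mean_mw = NA_real_, mean_logp = NA_real_))
  }
  w <- switch(weighting,
              paper_chebi_pairs = points$n_papers,
              recognitions = points$n_recognitions,
              unique = rep(1, nrow(points)))
  c(mean_mw = round(stats::weighted.mean(points$mw, w), 2),
    mean_logp = round(stats::weighted.mean(points$logp, w), 2))
}

#' Write a landscape grid as TSV plus a JSON sidecar
#'
#' The TSV has one row per non-empty cell (`logp_edge`, `mw_edge`,
#' `weight`, lower edges); the sidecar records totals, the weighting mode,
#' bin settings and the out-of-range count.
#'
#' @param landscape An `ldi_landscape`.
#' @param path Output TSV path; the sidecar is written alongside with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  nz <- which(landscape$weights > 0, arr.ind = TRUE)
  tab <- data.frame(
    logp_edge = landscape$logp_edges[nz[, 1]],
    mw_edge = landscape$mw_edges[nz[, 2]],
    weight = landscape$weights[nz]
  )
  tab <- tab[order(tab$logp_edge, tab$mw_edge), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    weighting = landscape$weighting,
    totals = landscape$totals,
    out_of_range = landscape$out_of_range,
    logp_range = range(landscape$logp_edges),
    logp_step = diff(landscape$logp_edges)[1],
    mw_range = range(landscape$mw_edges),
    mw_step = diff(landscape$mw_edges)[1]
  )
  jsonlite::write_json(sidecar, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
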