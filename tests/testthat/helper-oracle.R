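# Independent re-implementation of query evaluation, used as an oracle.
# Deliberately takes a different route from the engine: explicit token
# vectors and a sliding-window comparison instead of padded-string search.

oracle_tokens <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(character(0))
  toks <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

oracle_phrase_in <- function(phrase, tokens) {
  p <- oracle_tokens(phrase)
  np <- length(p)
  nt <- length(tokens)
  if (np == 0 || nt < np) return(FALSE)
  for (start in seq_len(nt - np + 1L)) {
    if (all(tokens[start:(start + np - 1L)] == p)) return(TRUE)
  }
  FALSE
}

oracle_match <- function(pub, q) {
  methods_toks <- oracle_tokens(pub$methods_text)
  all_fields <- list(oracle_tokens(pub$title), oracle_tokens(pub$abstract),
                     methods_toks)
  rec <- function(node) {
    switch(node$kind,
      term = {
        if (node$field == "methods") {
          oracle_phrase_in(node$phrase, methods_toks)
        } else {
          any(vapply(all_fields, function(t) oracle_phrase_in(node$phrase, t),
                     logical(1)))
        }
      },
      and = all(vapply(node$children, rec, logical(1))),
      or = any(vapply(node$children, rec, logical(1))),
      not = !rec(node$child)
    )
  }
  rec(q)
}

oracle_count <- function(corpus, q) {
  pubs <- corpus$publications
  sum(vapply(seq_len(nrow(pubs)), function(i) oracle_match(pubs[i, ], q),
             logical(1)))
}

# random corpora and query trees over a small shared vocabulary, so that
# random queries actually hit publications
oracle_vocab <- c("maldi", "matrix", "laser", "sample", "ion", "mass",
                  "spectrum", "acid", "small", "protein", "imaging",
                  "tissue", "drug", "metabolite", "surface")

random_text <- function(n_words) {
  paste(sample(oracle_vocab, n_words, replace = TRUE), collapse = " ")
}

random_oracle_corpus <- function(n_pubs = 100) {
  pubs <- tibble::tibble(
    pub_id = sprintf("P%04d", seq_len(n_pubs)),
    title = vapply(seq_len(n_pubs), function(i) random_text(5), ""),
    abstract = vapply(seq_len(n_pubs), function(i) random_text(25), ""),
    methods_text = ifelse(stats::runif(n_pubs) < 0.15, NA_character_,
                          vapply(seq_len(n_pubs),
                                 function(i) random_text(15), "")),
    pub_year = rep(NA_integer_, n_pubs),
    journal_year = rep(NA_integer_, n_pubs),
    first_pub_date = rep(NA_character_, n_pubs),
    electronic_pub_date = rep(NA_character_, n_pubs),
    first_index_date = rep(NA_character_, n_pubs),
    cited_by_count = rep(NA_integer_, n_pubs)
  )
  ldi_corpus(pubs)
}

random_query_tree <- function(depth = 3) {
  pick <- if (depth <= 0) "term" else
    sample(c("term", "and", "or", "not"), 1,
           prob = c(0.45, 0.2, 0.2, 0.15))
  switch(pick,
    term = query_term(paste(sample(oracle_vocab, sample(1:3, 1)),
                            collapse = " "),
                      field = sample(c("all", "methods"), 1,
                                     prob = c(0.7, 0.3))),
    and = do.call(query_and, lapply(seq_len(sample(2:3, 1)), function(i) {
      random_query_tree(depth - 1)
    })),
    or = do.call(query_or, lapply(seq_len(sample(2:3, 1)), function(i) {
      random_query_tree(depth - 1)
    })),
    not = query_not(random_query_tree(depth - 1))
  )
}

# fixture TSVs have leading '#' comment lines, but '#' also occurs inside
# SMILES (triple bonds), so only whole comment lines are stripped
read_fixture_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  utils::read.delim(text = paste(lines, collapse = "\n"),
                    stringsAsFactors = FALSE)
}

# tiny hand-built corpus used across unit tests
make_pub <- function(pub_id, title = NA, abstract = NA, methods = NA,
                     pub_year = NA, journal_year = NA, first_pub_date = NA,
                     electronic_pub_date = NA, first_index_date = NA,
                     cited_by_count = NA) {
  tibble::tibble(
    pub_id = pub_id,
    title = as.character(title), abstract = as.character(abstract),
    methods_text = as.character(methods),
    pub_year = as.integer(pub_year),
    journal_year = as.integer(journal_year),
    first_pub_date = as.character(first_pub_date),
    electronic_pub_date = as.character(electronic_pub_date),
    first_index_date = as.character(first_index_date),
    cited_by_count = as.integer(cited_by_count)
  )
}

tiny_corpus <- function() {
  ldi_corpus(dplyr::bind_rows(
    make_pub("P1", title = "MALDI imaging of drugs",
             abstract = "We analyzed small molecules in tissue.",
             methods = "Samples were measured by MALDI-TOF mass spectrometry.",
             pub_year = 2015, cited_by_count = 10),
    make_pub("P2", title = "Protein analysis",
             abstract = "A study of proteins and peptides with MALDI.",
             methods = "Electrospray ionization mass spectrometry was used.",
             first_pub_date = "2012-03-01", first_index_date = "2013-01-01",
             cited_by_count = 4),
    make_pub("P3", title = "Polymer characterization",
             abstract = "Polymers and oligomers were studied.",
             methods = NA)
  ))
}
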