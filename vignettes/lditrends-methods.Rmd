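---
title: "Methods: models, parameters and design choices in lditrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lditrends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lditrends)
```

# Scope

lditrends analyzes how laser desorption/ionization (LDI) techniques —
above all MALDI — are applied across analyte classes, using only
publication text and precomputed chemical annotations. Four stages are
connected: a boolean phrase query engine over publication records, matrix
co-occurrence enrichment statistics, VOSviewer input-file export, and
logP × molecular-weight landscapes of text-mined compounds. Everything
runs offline; a seeded synthetic-corpus generator supplies test corpora
with exact ground truth. VOSviewer's own term extraction, relevance
filtering, clustering and layout are out of scope — the package only
writes its input files. Likewise, named-entity recognition is consumed as
a precomputed annotation table, never performed.

# The query dialect

Publication text (title, abstract, methods) and query phrases are
lowercased and split on every non-alphanumeric character; a phrase
matches when its token sequence occurs contiguously. Three consequences
are intended and fixed:

* hyphens and slashes are token boundaries, so `MALDI` matches
  "MALDI-TOF" and "laser desorption/ionization" also matches the
  "desorption ionization" spelling;
* `MS` matches only as a whole token, never inside a longer word;
* a publication without a methods section fails every
  `METHODS:`-restricted term — there is no fallback to the abstract,
  since the restriction exists precisely to exclude mentions outside the
  experimental description.

Operator precedence is NOT > AND > OR. This dialect approximates, but is
not claimed identical to, the search semantics of large literature
databases (which may stem, or treat section boundaries differently); it
is the package's single point of truth for what "match" means, and the
synthetic generator is built around it.

Matching is implemented as one fixed-substring search per field over a
cached, space-padded token rendering of each publication; an independent
oracle used in the tests re-evaluates queries per publication with
explicit token windows.

# Enrichment statistics

For substance *s* and technique query *T* (always conjoined with the
mass-spectrometry guard), the co-occurrence row holds `total` = n(s),
`with_technique` = n(s ∧ T), and the three-way counts with the
small-molecule, peptide/protein and oligomer/polymer context queries
(plural-inclusive ORs, unrestricted fields). Substance queries OR over
all synonyms and are not METHODS-restricted, because a matrix may
legitimately be named anywhere in the text. The enrichment rule — at
least 5× the background fraction and at least 10 co-occurring
publications — is deliberately a plain threshold rule, not a significance
test: with corpus sizes in the tens of thousands, any nonzero enrichment
is "significant", and the rule's purpose is effect-size screening.

The background is the mean ± sample SD, in percent, of the technique
co-occurrence fraction over common non-matrix chemicals (adenosine,
alanine, ascorbic acid, chlorophyll, cholesterol, cisplatin, cocaine,
glucose, nicotine, water). Substances with no matching publications are
excluded with a warning rather than contributing a fictitious zero.

**Undefined ratios.** Every ratio with a zero denominator propagates as
`NA`, never as zero: a substance absent from the corpus has *no*
technique fraction, and collapsing that to 0 would silently mark it
maximally un-enriched.

**Weighted averages.** The pooled weighted average of SM/PP is
Σ with_sm / Σ with_pp — weights are the denominator counts. The source
material for this statistic does not state its weighting; the pooled form
is the default here because it is the only one that (a) reduces to the
row's own ratio for a single row and (b) is invariant to splitting a row
into parts with the same summed counts. A per-row mean weighted by
technique co-occurrence is available as `mode = "row_weighted"`; neither
mode is claimed to reproduce any particular published value, which also
depends on the live corpus state.

The 5% criterion compares `with_technique / total` — the fraction of the
*substance's* publications that also match the technique — because the
background is defined on the same substance-marginal scale.

# VOSviewer export

VOSviewer accepts no missing values, so export applies two imputation
rules. Years resolve through the field cascade pubYear → journal year of
publication → first publication date → electronic publication date →
first index date, each date contributing its year component; if all five
are absent, 2006 — the median publication year of the underlying
database — is imputed, and the provenance of every resolved year is
recorded. Missing citation counts become zero. The citations-per-age
score divides citations by age in whole years, clamped to a minimum of
one year: fractional ages from full dates would be possible but the
source fields are too inconsistently populated to support them, and the
clamp avoids division by zero for same-year publications. The reference
year defaults to 2023 (the retrieval date of the corpora the package's
reference tables derive from) and is configurable.

Minimum term-occurrence thresholds are normalized by corpus size:
`round(base_threshold × n/base_n)` with half-up rounding, clamped to ≥1.
With base 10 at 10 478 publications, an 80 806-publication corpus gets a
threshold of 77.

# Molecular properties

`compute_mw()` parses Hill-notation formulas (trailing charges ignored)
and sums IUPAC 2021 standard atomic weights, reported to 3 decimals.

`compute_logp()` implements the Wildman–Crippen (1999)
atomic-contribution method: hydrogens are made explicit, every atom
receives the contribution of the first matching atom type in the
published parameter table, and contributions are summed. The ordered
SMARTS table ships as a text resource; OpenBabel (via ChemmineOB)
supplies SMILES parsing and SMARTS matching, while the parameter table,
match ordering and summation live in this package. Two of the published
H-type patterns negate atom symbols (`[!C;!N;!O]`); in raw SMARTS
semantics that negation would let hydrogens on *aromatic* nitrogen fall
through to the alcohol-like class H2, contradicting the published atom
classes (any N–H is an amine hydrogen, H3). The shipped table therefore
writes these negations element-based (`[!#6;!#7;!#8]`). The test suite
verifies the implementation against an independent reference
implementation of the same method (RDKit, values frozen into a
51-molecule fixture) to 1e-3.

Property precedence for landscape points is: explicit `mw`/`logp` field
on the entity > value computed from formula/SMILES > exclusion with a
warning. Explicit fields win so that previously published property
tables can be ingested unchanged.

# Landscapes

The landscape grid has logP on x and molecular weight on y — chosen so
that a compound family with one logP and many masses (small
oligosaccharides, for instance) forms a vertical line. Default bins are
logP ∈ [−10, 15] in steps of 0.5 and MW ∈ [0, 1500] Da in steps of 25,
covering typical text-mined small-molecule corpora; both are
configurable. Cell weights count either publication–entity pairs (each
paper counts once per compound; the default, since repeat mentions
within one paper say more about writing style than usage) or raw
recognitions; totals for unique compounds, annotated papers, pairs and
recognitions are always recorded, and both weightings are exposed for
the summary means as well, since neither is canonically "the" average.
Out-of-range points are counted and reported, never silently clipped.
Compounds with the ChEBI role "MALDI matrix material" can be removed
before binning; removing before binning and subtracting their cells
after binning are verified to commute.

# The synthetic generator

The generator exists to make every stage testable without a network: it
emulates the *structure* of LDI literature corpora, not their language.
Each publication draws latent labels — technique indicators, analyte
contexts, substance mentions — and the exact query phrases are injected
into the appropriate fields, padded with filler words from a fixed
vocabulary that is asserted, at generation time, to share no token with
any query phrase. Injection is therefore lossless: query-engine output
equals the latent labels, publication by publication. This is the basis
for the exact pipeline-vs-truth equality checks in the tests.

Model and defaults (one corpus-level seed; fixed seed ⇒ byte-identical
corpora):

* **Techniques.** MALDI at prevalence 0.25 and SALDI at 0.05 —
  reflecting that in a matrix-centred corpus the main technique is
  common but not majority. Every publication carries the
  mass-spectrometry guard phrase in its methods (rate 1.0,
  configurable).
* **Matrix substances.** Mention probability 0.3–0.8 given the
  technique; off-technique rate log-uniform over 0.002–0.2, so that (as
  in the real literature) some matrices co-occur with the technique
  almost always and others have substantial other uses.
* **Non-matrix chemicals.** Calibrated to a target background: with
  technique prevalence π and target b = 0.01, the mention probability
  given the technique is p₀·b(1−π)/((1−b)π) against p₀ ∈ 0.05–0.15
  without, making the realized technique co-occurrence fraction an
  unbiased estimate of b (the ~1% background regime).
* **Contexts.** P(peptide/protein | technique) = 0.45,
  small-molecule 0.15, oligomer/polymer 0.15; base rates 0.08/0.03/0.03
  — peptides/proteins dominate the technique literature.
* **Analyte classes.** Metabolite-like (120 entities,
  MW ~ logN(log 200, 0.5), logP ~ N(0.5, 1)), oligosaccharide-like (40,
  logN(log 450, 0.35), logP ~ N(−2.3, 0.25) — the vertical-line family),
  lipid-like (40, logN(log 700, 0.3), logP ~ N(7, 1.5)). Entities carry
  explicit mw/logp values; matrix substances additionally get entities
  bearing the "MALDI matrix material" role, annotated wherever the
  substance is mentioned.
* **Years.** Each publication's year provenance is drawn directly from
  a categorical distribution (pubYear 0.78, journal year 0.05, first
  publication date 0.06, electronic date 0.04, index date 0.04,
  all-absent 0.03) and the five fields are then populated consistently:
  fields earlier in the resolution order absent, the chosen field
  present, later fields present at random. Sampling provenance directly
  (rather than five independent presence coins) makes the resolved
  provenance checkable per publication, not merely in expectation.
* **Citations.** Negative-binomial with mean 2 × age and dispersion
  1.2 — overdispersed, and age-proportional so the citations-per-age
  score has a flat expectation (verified by a regression-slope test);
  the citation field is absent with probability 0.03.
* The generator uses a single seeded R random stream with a fixed
  sampling order rather than per-publication counter substreams; this
  gives the same guarantee that matters — byte-identical corpora for a
  fixed seed — with R's native RNG machinery.

What passing tests on synthetic corpora do **not** show: robustness to
real NER errors, acronym ambiguity (FAB the ionization source vs Fab the
antibody fragment — deliberately not disambiguated), stemming and
section-detection quirks of live databases, or duplicated
preprint/journal records (no deduplication is performed anywhere). The
generator produces no such artifacts, by design.

# Numerical and degenerate-input choices

* Ratios: undefined (`NA`) on zero denominators throughout sorting and
  reporting; machine output carries 3 decimals, display tables 2.
* `normalized_min_occurrences` rounds half-up and floors at 1.
* Publication ages clamp to ≥ 1 year.
* Empty corpora, empty annotation sets and all-filtered landscapes yield
  empty-but-well-formed objects (zero totals), not errors.
* Duplicate (publication, compound) annotation rows are summed on load —
  annotation feeds report per-sentence hits.
* Empty strings and missing fields in records are both treated as
  absent, and absences survive a write/read round trip; imputation is an
  export-time rule only.

# Problem sizes used in the checks

The pipeline-vs-truth equality and parameter-recovery checks run on a
10 000-publication synthetic corpus; statistical recoveries are asserted
at 3 standard errors. The query-engine/oracle equivalence uses 200
random query trees over 100-publication corpora; cross-implementation
logP agreement uses a 51-molecule fixture at 1e-3. Unit tests use
corpora of 1–6 000 publications.

# Known limitations

* The matching dialect is one fixed interpretation of phrase search;
  counts from live databases will differ wherever their tokenization,
  stemming or section detection differs.
* Enrichment is a screening rule; it provides no error control and
  inherits all reporting biases of the literature (working
  matrix–analyte combinations are far likelier to be mentioned than
  failures).
* The logP calculator is exactly the Wildman–Crippen model: no
  ionization-state handling, no 3D effects; published landscape averages
  from other pipelines need not be reproducible with it.
* The synthetic generator's distributional choices are stand-ins chosen
  for realism and testability, not estimates fitted to any corpus.
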