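# Molecular weight from Hill-notation formulas, and Wildman-Crippen logP
# from SMILES. The logP calculator implements the atomic-contribution
# method of Wildman & Crippen (1999): every atom (hydrogens made explicit)
# is assigned the first matching atom type in the published parameter
# table, and logP is the sum of the per-atom contributions. OpenBabel
# (through ChemmineOB's low-level bindings) supplies SMILES parsing and
# SMARTS matching; the parameter table and the typing/summation logic live
# in this package.

# IUPAC 2021 standard atomic weights, abridged to the precision used in
# common molecular-weight calculators.
ATOMIC_WEIGHTS <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990,
  Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, Ar = 39.95, K = 39.098, Ca = 40.078, Sc = 44.956,
  Ti = 47.867, V = 50.942, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Ga = 69.723,
  Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904, Kr = 83.798,
  Rb = 85.468, Sr = 87.62, Y = 88.906, Zr = 91.224, Nb = 92.906,
  Mo = 95.95, Ru = 101.07, Rh = 102.91, Pd = 106.42, Ag = 107.87,
  Cd = 112.41, In = 114.82, Sn = 118.71, Sb = 121.76, Te = 127.60,
  I = 126.90, Xe = 131.29, Cs = 132.91, Ba = 137.33, La = 138.91,
  Ce = 140.12, Pr = 140.91, Nd = 144.24, Sm = 150.36, Eu = 151.96,
  Gd = 157.25, Tb = 158.93, Dy = 162.50, Ho = 164.93, Er = 167.26,
  Tm = 168.93, Yb = 173.05, Lu = 174.97, Hf = 178.49, Ta = 180.95,
  W = 183.84, Re = 186.21, Os = 190.23, Ir = 192.22, Pt = 195.08,
  Au = 196.97, Hg = 200.59, Tl = 204.38, Pb = 207.2, Bi = 208.98,
  Th = 232.04, Pa = 231.04, U = 238.03
)

#' Parse a molecular formula into element counts
#'
#' Accepts Hill-notation formulas such as `C6H12O6`. A trailing charge
#' (`+`, `-`, `2-`, ...) is ignored.
#'
#' @param formula Formula string.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || is.na(formula) ||
      !nzchar(trimws(formula))) {
    stop("empty molecular formula", call. = FALSE)
  }
  f <- trimws(formula)
  f <- sub("\\s*[0-9]*[+-]$", "", f)  # drop charge suffix
  counts <- integer(0)
  while (nzchar(f)) {
    m <- regexpr("^([A-Z][a-z]?)([0-9]*)", f)
    if (m == -1L || attr(m, "match.length") == 0L) {
      stop("cannot parse formula '", formula, "' at '", f, "'", call. = FALSE)
    }
    piece <- regmatches(f, m)
    sym <- sub("^([A-Z][a-z]?).*", "\\1", piece)
    num <- sub("^[A-Z][a-z]?", "", piece)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% names(ATOMIC_WEIGHTS)) {
      # a two-letter guess like "Og" may really be one known element + lowercase
      stop("unknown element symbol '", sym, "' in formula '", formula, "'",
           call. = FALSE)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    f <- substr(f, attr(m, "match.length") + 1L, nchar(f))
  }
  counts
}

#' Molecular weight from a molecular formula
#'
#' Average molecular weight in Da: the sum over elements of count times the
#' IUPAC 2021 standard atomic weight, reported to 3 decimals.
#'
#' @param formula Hill-notation formula string (vectorized).
#' @return Numeric vector of molecular weights (Da).
#' @export
#' @examples
#' compute_mw("H2O")     # 18.015
#' compute_mw("C6H12O6") # 180.156
compute_mw <- function(formula) {
  vapply(formula, function(f) {
    counts <- parse_formula(f)
    round(sum(counts * ATOMIC_WEIGHTS[names(counts)]), 3)
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- Wildman-Crippen logP --------------------------------------------------

.wc_cache <- new.env(parent = emptyenv())

wc_params <- function() {
  if (is.null(.wc_cache$params)) {
    path <- system.file("extdata", "wildman_crippen_logp.tsv",
                        package = "lditrends", mustWork = TRUE)
    # SMARTS patterns contain '#', so only leading comment lines are dropped
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    .wc_cache$params <- utils::read.delim(text = paste(lines, collapse = "\n"),
                                          stringsAsFactors = FALSE)
  }
  .wc_cache$params
}

ob <- function() {
  if (is.null(.wc_cache$ns)) {
    .wc_cache$ns <- asNamespace("ChemmineOB")
  }
  .wc_cache$ns
}

wc_patterns <- function() {
  if (is.null(.wc_cache$patterns)) {
    ns <- ob()
    params <- wc_params()
    .wc_cache$patterns <- lapply(params$smarts, function(s) {
      sp <- ns$OBSmartsPattern()
      if (!ns$OBSmartsPattern_Init(sp, s)) {
        stop("failed to compile SMARTS pattern: ", s)
      }
      sp
    })
  }
  .wc_cache$patterns
}

read_obmol <- function(smiles) {
  ns <- ob()
  conv <- ns$OBConversion()
  ns$OBConversion_SetInFormat(conv, "smi")
  mol <- ns$OBMol()
  ok <- ns$OBConversion_ReadString(conv, mol, smiles)
  if (!isTRUE(ok) || ns$OBMol_NumAtoms(mol) == 0) {
    stop("unparseable SMILES: ", smiles, call. = FALSE)
  }
  ns$OBMol_AddHydrogens(mol)
  mol
}

#' Wildman-Crippen logP from SMILES
#'
#' Atomic-contribution estimate of the octanol/water partition coefficient.
#' Hydrogens are made explicit, each atom receives the contribution of the
#' first atom type in the published parameter table whose SMARTS pattern
#' matches it, and the contributions are summed. Deterministic; no
#' conformer or 3D information is used.
#'
#' Entities carrying a precomputed `logp` value bypass computation (see
#' `precomputed`), which lets published property tables be ingested as-is.
#'
#' @param smiles SMILES string (vectorized).
#' @param precomputed Optional numeric vector of the same length; where
#'   non-`NA`, that value is returned unchanged.
#' @return Numeric vector of logP estimates.
#' @export
#' @examples
#' \dontrun{
#' compute_logp("CCO")              # ethanol, about 0.0
#' compute_logp("c1ccccc1")         # benzene, about 1.69
#' }
compute_logp <- function(smiles, precomputed = NULL) {
  n <- length(smiles)
  out <- numeric(n)
  pre <- precomputed %||% rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(pre[i])) {
      out[i] <- pre[i]
      next
    }
    out[i] <- wc_logp_one(smiles[i])
  }
  out
}

wc_logp_one <- function(smiles) {
  ns <- ob()
  mol <- read_obmol(smiles)
  params <- wc_params()
  pats <- wc_patterns()
  natoms <- ns$OBMol_NumAtoms(mol)
  contrib <- rep(NA_real_, natoms)
  for (i in seq_along(pats)) {
    if (!ns$OBSmartsPattern_Match(pats[[i]], mol)) next
    maps <- ns$OBSmartsPattern_GetMapList(pats[[i]])
    for (m in maps) {
      a <- m[1]
      if (is.na(contrib[a])) contrib[a] <- params$logp[i]
    }
    if (!anyNA(contrib)) break
  }
  sum(contrib, na.rm = TRUE)
}
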