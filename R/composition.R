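# Elemental compositions as named integer vectors (symbols C, H, D, N, O, P,
# S; "D" is the deuterium label, chemically 2H but frozen during isotope
# convolution). Monoisotopic masses come from the packaged abundance table so
# that mass and envelope calculations can never disagree.

ELECTRON_MASS <- 0.000548579909

the <- new.env(parent = emptyenv())

#' Natural isotope abundance table
#'
#' Per-element isotopic masses and natural abundances, indexed by the nominal
#' mass shift relative to the lightest isotope. The table is shipped as
#' plain text under `inst/extdata/isotope_abundances.tsv`; editing that file
#' (e.g. to adopt a different IUPAC revision) is a configuration change.
#'
#' @param path Optional path to an alternative abundance table.
#' @return A tibble with columns `element`, `shift`, `mass`, `abundance`.
#' @export
isotope_abundances <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(the$abundances)) {
      the$abundances <- readr::read_tsv(
        system.file("extdata", "isotope_abundances.tsv", package = "lipidpipe"),
        col_types = "cidd", progress = FALSE
      )
    }
    return(the$abundances)
  }
  readr::read_tsv(path, col_types = "cidd", progress = FALSE)
}

monoisotopic_masses <- function() {
  ab <- isotope_abundances()
  ab <- ab[ab$shift == 0, ]
  stats::setNames(ab$mass, ab$element)
}

#' Parse a molecular formula into an element count vector
#'
#' @param formula A Hill-style formula string such as `"C42H80NO8P"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)(\\d*)", formula, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != formula) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("\\d+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (is.na(counts[el])) 0L else counts[el]) + n
  }
  counts[is.na(counts)] <- 0L
  counts
}

comp_zero <- function() {
  stats::setNames(integer(7), c("C", "H", "D", "N", "O", "P", "S"))
}

comp_canon <- function(x) {
  out <- comp_zero()
  extra <- setdiff(names(x), names(out))
  if (length(extra)) out[extra] <- 0L
  out[names(x)] <- out[names(x)] + as.integer(round(x))
  out
}

comp_add <- function(a, b, scale = 1L) {
  a <- comp_canon(a)
  b <- comp_canon(b)
  nm <- union(names(a), names(b))
  av <- stats::setNames(integer(length(nm)), nm)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  av + as.integer(scale) * bv
}

comp_check <- function(x, context = "composition") {
  if (any(x < 0)) {
    stop(context, " has negative element counts (",
         paste(names(x)[x < 0], collapse = ", "), ")", call. = FALSE)
  }
  x
}

#' Format an element count vector as a formula string
#'
#' @param comp Named integer vector of element counts.
#' @return A Hill-ordered formula string (deuterium printed as `D`).
#' @export
format_formula <- function(comp) {
  comp <- comp_canon(comp)
  ord <- c("C", "H", "D", "N", "O", "P", "S")
  parts <- vapply(ord, function(el) {
    n <- comp[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste(parts, collapse = "")
}

#' Monoisotopic mass of an elemental composition
#'
#' @param comp Named integer vector of element counts (or a formula string).
#' @return Monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  if (is.character(comp)) comp <- parse_formula(comp)
  comp <- comp_canon(comp)
  masses <- monoisotopic_masses()
  missing <- setdiff(names(comp)[comp > 0], names(masses))
  if (length(missing)) {
    stop("no mass data for element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(comp[comp > 0] * masses[names(comp)[comp > 0]])
}

# Adduct definitions. Deltas are compositions relative to the neutral M;
# m/z = (mass(M) + mass(delta) - charge * electron_mass) / |charge|.
ADDUCTS <- list(
  "[M+H]+"      = list(delta = c(H = 1L), charge = +1L),
  "[M+NH4]+"    = list(delta = c(N = 1L, H = 4L), charge = +1L),
  "[M+H-H2O]+"  = list(delta = c(H = -1L, O = -1L), charge = +1L),
  "[M-H]-"      = list(delta = c(H = -1L), charge = -1L),
  "[M+CH3COO]-" = list(delta = c(C = 2L, H = 3L, O = 2L), charge = -1L)
)

#' Supported adduct names
#' @return Character vector of adduct names understood by [adduct_mz()].
#' @export
adduct_names <- function() names(ADDUCTS)

adduct_def <- function(name) {
  def <- ADDUCTS[[name]]
  if (is.null(def)) {
    stop("unknown adduct: ", name, " (supported: ",
         paste(names(ADDUCTS), collapse = ", "), ")", call. = FALSE)
  }
  def
}

#' m/z of a neutral composition under an adduct
#'
#' All adducts used here are singly charged; the electron mass is included so
#' that ppm-level accuracy holds down to low m/z.
#'
#' @param comp Neutral composition (named counts or formula string).
#' @param adduct Adduct name, one of [adduct_names()].
#' @return m/z in Da.
#' @export
adduct_mz <- function(comp, adduct) {
  if (is.character(comp)) comp <- parse_formula(comp)
  def <- adduct_def(adduct)
  ion <- comp_add(comp, def$delta)
  comp_check(ion, paste0("ion composition for ", adduct))
  (monoisotopic_mass(ion) - def$charge * ELECTRON_MASS) / abs(def$charge)
}
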