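# Elemental-formula algebra and monoisotopic ion m/z.
#
# Formulas are named integer vectors (element symbol -> count). All mass
# arithmetic in the package funnels through these functions so that every
# diagnostic-ion and precursor match uses one isotope mass table.

# Monoisotopic (most abundant isotope) masses, IUPAC/CODATA, 7 decimals.
.MONO_MASS <- c(
  C  = 12.0000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  S  = 31.9720707,
  Na = 22.9897693,
  K  = 38.9637065,
  Cl = 34.9688527
)

# Electron rest mass in Da; applied when converting an ion formula to m/z.
.ELECTRON_MASS <- 0.0005486

#' Parse an elemental formula string
#'
#' Parses a compact formula string such as `"C27H54O12P"` into a named
#' integer vector of element counts. Elements absent from the string get
#' count 0 on arithmetic, not an entry.
#'
#' @param text A formula string: element symbols (one uppercase letter,
#'   optionally one lowercase letter) each followed by an optional positive
#'   integer count.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H13O9P")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) stop("formula string is NA")
  text <- gsub("[[:space:]]", "", text)
  if (text == "") {
    return(structure(integer(0), names = character(0)))
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1L]]
  parts <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  if (sum(nchar(parts)) != nchar(text)) {
    stop("malformed formula string: ", sQuote(text))
  }
  counts <- integer(0)
  for (p in parts) {
    sym <- sub("[0-9]*$", "", p)
    num <- sub("^[A-Za-z]+", "", p)
    n <- if (num == "") 1L else as.integer(num)
    if (!sym %in% names(.MONO_MASS)) {
      stop("unknown element symbol ", sQuote(sym), " in ", sQuote(text))
    }
    if (is.na(n) || n < 1L) stop("malformed count in token ", sQuote(p))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  counts
}

#' Serialize a formula to canonical Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' count 1 is left implicit. The composition of [parse_formula()] and
#' `format_formula()` is the identity on canonical strings.
#'
#' @param f Named integer vector of element counts.
#' @return A single formula string (`""` for the empty formula).
#' @export
format_formula <- function(f) {
  f <- f[f != 0]
  if (length(f) == 0L) return("")
  syms <- names(f)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  paste0(vapply(ord, function(s) {
    n <- f[[s]]
    if (n == 1L) s else paste0(s, n)
  }, character(1)), collapse = "")
}

#' Add two elemental formulas
#' @param a,b Named integer vectors of element counts.
#' @return Named integer vector; elementwise sum.
#' @export
formula_add <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) + (if (s %in% names(b)) b[[s]] else 0L)
  }, numeric(1))
  out <- as.integer(round(out))
  names(out) <- syms
  out[out != 0L]
}

#' Subtract one elemental formula from another
#'
#' Embodies a neutral loss: `a - b` must leave non-negative counts.
#'
#' @param a,b Named integer vectors of element counts.
#' @return Named integer vector; elementwise difference.
#' @export
formula_subtract <- function(a, b) {
  syms <- union(names(a), names(b))
  out <- vapply(syms, function(s) {
    (if (s %in% names(a)) a[[s]] else 0L) - (if (s %in% names(b)) b[[s]] else 0L)
  }, numeric(1))
  neg <- syms[out < 0]
  if (length(neg)) {
    stop("formula subtraction gives negative count for element(s): ",
         paste(neg, collapse = ", "))
  }
  out <- as.integer(round(out))
  names(out) <- syms
  out[out != 0L]
}

#' Monoisotopic mass of a neutral formula
#'
#' @param f Named integer vector of element counts, or a formula string.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L) return(0)
  unknown <- setdiff(names(f), names(.MONO_MASS))
  if (length(unknown)) {
    stop("no isotope mass for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.MONO_MASS[names(f)] * as.numeric(f))
}

#' m/z of a singly charged ion
#'
#' The formula is taken as that of the ion as written (charge carriers
#' included, e.g. `C27H54O12P` for an \[M+H\]+ species); the electron mass
#' is subtracted for cations and added for anions. Printed high-resolution
#' values in the low-hundreds m/z range drift by ~3 ppm if the electron
#' correction is omitted, so it is always applied.
#'
#' @param formula Ion formula (named integer vector or string).
#' @param charge `+1` or `-1`.
#' @return m/z in Da.
#' @examples
#' ion_mz("C5H15NO4P", +1) # phosphocholine cation, 184.0733
#' ion_mz("C3H8O6P", -1)   # glycerophosphate anion, 171.0064
#' @export
ion_mz <- function(formula, charge) {
  if (!charge %in% c(-1L, 1L, -1, 1)) {
    stop("only singly charged ions are supported (charge must be +1 or -1)")
  }
  monoisotopic_mass(formula) - sign(charge) * .ELECTRON_MASS
}

#' Signed parts-per-million mass error
#'
#' @param observed,theoretical m/z values in Da; `theoretical` must be > 0.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Adduct ion of a neutral molecule
#'
#' Builds the singly protonated or deprotonated ion of a neutral formula,
#' the only adducts the annotation engine considers.
#'
#' @param neutral Neutral molecule formula (named integer vector or
#'   string).
#' @param adduct `"[M+H]+"` or `"[M-H]-"`.
#' @return List with `formula` (ion element counts), `charge` and `label`.
#' @export
adduct_ion <- function(neutral, adduct = c("[M+H]+", "[M-H]-")) {
  adduct <- match.arg(adduct)
  if (is.character(neutral)) neutral <- parse_formula(neutral)
  H1 <- c(H = 1L)
  if (adduct == "[M+H]+") {
    list(formula = formula_add(neutral, H1), charge = +1L, label = adduct)
  } else {
    list(formula = formula_subtract(neutral, H1), charge = -1L, label = adduct)
  }
}

#' m/z of the adduct ion of a neutral formula
#'
#' @param neutral Neutral molecule formula (named integer vector or
#'   string).
#' @param polarity `"positive"` (gives `[M+H]+`) or `"negative"`
#'   (`[M-H]-`).
#' @return m/z in Da.
#' @export
adduct_mz <- function(neutral, polarity) {
  ion <- adduct_ion(neutral, if (polarity == "positive") "[M+H]+" else "[M-H]-")
  ion_mz(ion$formula, ion$charge)
}
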