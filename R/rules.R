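# Diagnostic-ion rulebook for lipid class recognition.
#
# One rule = one lipid class x polarity: fixed-m/z diagnostic ions,
# neutral losses applied to the precursor, and the chain-release losses
# whose complementary fragment carries the fatty chain. Classes covered:
# glycerophosphoinositols (GPI), -glycerols (GPG), -ethanolamines (GPE),
# -phosphates (GPA, plus cyclic cGPA), -serines (GPS), -cholines (GPC),
# inositol phosphorylceramides (IPC) and prostaglandin-type oxylipins (PG).

# Headgroup + glycerol backbone of each glycerophospholipid class, as the
# neutral formula of the chain-free (di-hydroxy) parent.
.BACKBONE <- list(
  GPI  = "C9H19O11P",  # glycerophosphoinositol
  GPG  = "C6H15O8P",   # glycerophosphoglycerol
  GPE  = "C5H14NO6P",  # glycerophosphoethanolamine
  GPA  = "C3H9O6P",    # glycerophosphoric acid
  cGPA = "C3H7O5P",    # cyclic glycerophosphate
  GPS  = "C6H14NO8P",  # glycerophosphoserine
  GPC  = "C8H20NO6P"   # glycerophosphocholine
)

# Display class: cyclic GPA is counted within the GP chemical class.
.CHEM_CLASS <- c(GPI = "GPI", GPG = "GPG", GPE = "GPE", GPA = "GP",
                 cGPA = "GP", GPS = "GPS", GPC = "GPC", IPC = "IPC", PG = "PG")

# Fixed tie-break priority between equally supported class candidates.
.CLASS_PRIORITY <- c("GPC", "GPE", "GPS", "GPI", "GPG", "GPA", "cGPA", "IPC", "PG")

.rule_item <- function(kind, formula) list(kind = kind, formula = formula)
.ion <- function(f) .rule_item("ion", f)
.loss <- function(f) .rule_item("loss", f)

#' Built-in lipid class rules
#'
#' Returns the rulebook of diagnostic ions and neutral losses for the nine
#' class/polarity rulesets the annotator knows. Each rule lists `required`
#' items (at least `min_required` must match for the class to become a
#' candidate), `supporting` items (used for ranking), and `chain_release`
#' losses whose complement pins the fatty chain. Ion entries are the ion
#' formula as charged (e.g. the phosphocholine cation `C5H15NO4P` at m/z
#' 184.0733); loss entries are neutral formulas subtracted from the
#' precursor ion.
#'
#' @return A list of rules; each rule is a list with elements `class_id`,
#'   `polarity`, `required`, `supporting`, `chain_release`, `min_required`.
#' @export
builtin_rules <- function() {
  rules <- list(
    list(class_id = "GPI", polarity = "positive", min_required = 1L,
         required = list(
           .ion("C9H20O11P"),    # glycerylphosphorylinositol cation, 335.0738
           .ion("C6H14O9P"),     # phosphorylinositol cation, 261.0370
           .loss("C6H13O9P")),   # inositol phosphate loss (dominant)
         supporting = list(
           .ion("C9H18O10P"),    # 335 - H2O
           .ion("C6H12O8P"),     # 261 - H2O
           .loss("H2O")),
         chain_release = list(.loss("C9H19O11P"), .loss("C6H12O6"))),
    list(class_id = "GPI", polarity = "negative", min_required = 1L,
         required = list(
           .ion("C6H12O9P")),    # phosphorylinositol anion, 259.0224
         supporting = list(
           .ion("C9H18O11P"),    # glycerylphosphorylinositol anion, 333.0592
           .ion("C9H16O10P"),    # 333 - H2O, 315.0487
           .ion("C6H10O8P"),     # 259 - H2O, 241.0119
           .ion("C6H8O7P"),      # 259 - 2 H2O
           .ion("C3H8O6P"),      # glycerophosphate, 171.0064
           .ion("C3H6O5P")),     # 171 - H2O, 152.9958
         chain_release = list(.loss("C9H17O10P"))),
    list(class_id = "GPG", polarity = "positive", min_required = 1L,
         required = list(
           .ion("C6H16O8P"),     # glycerylphosphorylglycerol cation, 247.0577
           .ion("C3H10O6P")),    # glycerophosphoric acid cation, 173.0210
         supporting = list(
           .ion("C6H14O7P"),     # 247 - H2O
           .ion("C3H8O5P"),      # 173 - H2O
           .loss("H2O")),
         chain_release = list(.loss("C3H7O5P"), .loss("C3H6O2"))),
    list(class_id = "GPG", polarity = "negative", min_required = 1L,
         required = list(
           .ion("C6H14O8P"),     # glycerylphosphorylglycerol anion, 245.0432
           .loss("C3H6O2")),     # glycerol loss (monoalkyl species)
         supporting = list(
           .ion("C6H12O7P"),     # 245 - H2O
           .ion("C3H8O6P"),      # 171.0064
           .ion("C3H6O5P")),
         chain_release = list(.loss("C6H13O7P"))),
    list(class_id = "GPE", polarity = "positive", min_required = 1L,
         required = list(
           .loss("C2H8NO4P")),   # phosphoethanolamine loss
         supporting = list(
           .loss("H2O"),
           .loss("C2H5N"),       # aziridine rearrangement loss
           .loss("C2H7NO"),      # ethanolamine loss
           .loss("C3H9O6P")),    # internal glycerophosphoric acid loss
         chain_release = list(.loss("C2H8NO4P"))),
    list(class_id = "GPE", polarity = "negative", min_required = 1L,
         required = list(
           .ion("C5H13NO6P"),    # glycerophosphoethanolamine anion, 214.0486
           .ion("C2H7NO4P"),     # phosphoethanolamine anion, 140.0118
           .loss("C5H12NO5P")),  # glycerophosphoethanolamine loss (dominant)
         supporting = list(
           .ion("C5H11NO5P"),    # 214 - H2O
           .ion("C3H6O5P")),     # 152.9958
         chain_release = list(.loss("C5H12NO5P"))),
    list(class_id = "GPA", polarity = "positive", min_required = 1L,
         required = list(
           .loss("H3O4P"),       # phosphoric acid loss, -97.9769
           .ion("C3H10O6P")),    # glycerophosphoric acid cation, 173.0210
         supporting = list(.loss("H2O")),
         chain_release = list(.loss("H3O4P"))),
    list(class_id = "GPA", polarity = "negative", min_required = 1L,
         required = list(
           .ion("H2O4P"),        # phosphoric acid anion, 96.9696
           .loss("C3H7O5P")),    # glycerophosphate loss -> carboxylate
         supporting = list(.ion("C3H8O6P")),
         chain_release = list(.loss("C3H7O5P"))),
    list(class_id = "cGPA", polarity = "negative", min_required = 2L,
         required = list(
           .ion("C3H6O5P"),      # cyclic glycerophosphate anion, 152.9958
           .loss("C3H5O4P")),    # cyclic glycerophosphoric acid loss
         supporting = list(),
         chain_release = list(.loss("C3H5O4P"))),
    list(class_id = "GPS", polarity = "positive", min_required = 1L,
         required = list(
           .ion("C6H15NO8P"),    # glycerophosphoserine cation, 260.0530
           .loss("C3H8NO6P"),    # phosphoserine loss
           .loss("C3H7NO3")),    # serine loss
         supporting = list(
           .ion("C6H13NO7P"),    # 260 - H2O
           .ion("C3H8NO3"),      # serine cation, 106.0503
           .ion("C3H6NO2"),      # 106 - H2O, 88.0393
           .loss("H2O")),
         chain_release = list(.loss("C3H8NO6P"), .loss("C3H7NO3"))),
    list(class_id = "GPS", polarity = "negative", min_required = 1L,
         required = list(
           .loss("C3H5NO2"),     # serine residue loss
           .loss("C6H12NO7P")),  # glycerophosphoserine loss -> carboxylate
         supporting = list(
           .loss("C3H7NO3"),     # serine loss (dehydrated cognate)
           .ion("C3H8O6P")),     # 171.0064
         chain_release = list(.loss("C6H12NO7P"))),
    list(class_id = "GPC", polarity = "positive", min_required = 1L,
         required = list(
           .ion("C5H15NO4P")),   # phosphocholine cation, 184.0733
         supporting = list(
           .ion("C5H14NO"),      # choline headgroup, 104.1070
           .ion("C8H21NO6P"),    # glycerylphosphorylcholine, 258.1101
           .ion("C8H19NO5P"),    # 258 - H2O
           .loss("H2O")),
         chain_release = list(.loss("C5H14NO4P"))),  # -183.0655
    list(class_id = "IPC", polarity = "positive", min_required = 1L,
         required = list(
           .loss("C6H15O10P")),  # H2O + inositol monophosphate C6H13O9P
         supporting = list(
           .loss("C6H17O11P"),   # 2 H2O + inositol monophosphate
           .loss("H2O")),
         chain_release = list()),  # ketene-combined losses handled in infer_chain
    list(class_id = "IPC", polarity = "negative", min_required = 3L,
         required = list(
           .ion("C6H12O9P"),     # inositol monophosphate anion, 259.0224
           .ion("C6H10O8P"),     # inositol-1,2-cyclic phosphate anion, 241.0119
           .loss("C6H10O5")),    # anhydro-inositol loss
         supporting = list(
           .loss("C6H12O6")),    # anhydro-inositol + H2O
         chain_release = list()),
    list(class_id = "PG", polarity = "negative", min_required = 2L,
         required = list(
           .loss("H2O"),
           .loss("H4O2"),        # 2 H2O
           .loss("CH2O3"),       # H2O + CO2
           .loss("CO2")),
         supporting = list(.loss("CH4O4")),  # 2 H2O + CO2
         chain_release = list())
  )
  # precompute theoretical m/z / loss masses once
  lapply(rules, function(rule) {
    chg <- if (rule$polarity == "positive") +1L else -1L
    annotate_items <- function(items) {
      lapply(items, function(it) {
        it$mass <- monoisotopic_mass(it$formula)
        if (it$kind == "ion") it$mz <- ion_mz(it$formula, chg)
        it
      })
    }
    rule$required <- annotate_items(rule$required)
    rule$supporting <- annotate_items(rule$supporting)
    rule$chain_release <- annotate_items(rule$chain_release)
    rule$charge <- chg
    rule
  })
}

#' Annotation engine parameters
#'
#' @param fragment_tol_da,fragment_tol_ppm Fragment match tolerance: the
#'   larger of `fragment_tol_da` and `fragment_tol_ppm` at the fragment's
#'   m/z is used.
#' @param precursor_tol_ppm Precursor formula match tolerance in ppm.
#' @param chain_carbons,chain_db,chain_oxygens Inclusive bounds on total
#'   chain carbons, chain double bonds and extra (oxidation) oxygens.
#' @param class_priority Tie-break order between class candidates.
#' @return A list of class `annotation_params`.
#' @export
annotation_params <- function(fragment_tol_da = 0.005,
                              fragment_tol_ppm = 10,
                              precursor_tol_ppm = 5,
                              chain_carbons = c(10L, 44L),
                              chain_db = c(0L, 8L),
                              chain_oxygens = c(0L, 4L),
                              class_priority = .CLASS_PRIORITY) {
  stopifnot(fragment_tol_da > 0, fragment_tol_ppm > 0, precursor_tol_ppm > 0)
  structure(list(fragment_tol_da = fragment_tol_da,
                 fragment_tol_ppm = fragment_tol_ppm,
                 precursor_tol_ppm = precursor_tol_ppm,
                 chain_carbons = as.integer(chain_carbons),
                 chain_db = as.integer(chain_db),
                 chain_oxygens = as.integer(chain_oxygens),
                 class_priority = class_priority),
            class = "annotation_params")
}

# fragment-match tolerance in Da at a given m/z
.frag_tol <- function(mz, params) {
  pmax(params$fragment_tol_da, params$fragment_tol_ppm * 1e-6 * mz)
}

# Does the spectrum contain a peak at mz (within tolerance)? Returns the
# matched peak index or NA.
.find_peak <- function(s, mz, params) {
  if (!length(s$mz)) return(NA_integer_)
  d <- abs(s$mz - mz)
  i <- which.min(d)
  if (d[i] <= .frag_tol(mz, params)) i else NA_integer_
}

# Match one rule item against a spectrum; returns NULL or a one-row
# data.frame of evidence.
.match_item <- function(s, item, params) {
  target <- if (item$kind == "ion") item$mz else s$precursor_mz - item$mass
  if (target <= 0) return(NULL)
  i <- .find_peak(s, target, params)
  if (is.na(i)) return(NULL)
  data.frame(kind = item$kind, formula = item$formula,
             expected_mz = target, matched_mz = s$mz[i],
             intensity = s$intensity[i],
             ppm = ppm_error(s$mz[i], target),
             stringsAsFactors = FALSE)
}

#' Rank lipid class candidates for a spectrum
#'
#' A class becomes a candidate when at least `min_required` of its
#' required diagnostic items match (a diagnostic ion within the fragment
#' tolerance, or a neutral-loss peak at precursor minus loss). Candidates
#' are ranked by required matches, then supporting matches, then summed
#' matched intensity, with ties broken by the fixed class priority.
#'
#' @param s An [ms2_spectrum].
#' @param rules Rule list from [builtin_rules()].
#' @param params An [annotation_params()] list.
#' @return Data frame of candidates (class_id, n_required, n_supporting,
#'   matched_intensity) in rank order, with the per-candidate evidence in
#'   attribute `"evidence"` (a list of data frames). Zero rows if nothing
#'   matches.
#' @export
detect_class <- function(s, rules = builtin_rules(), params = annotation_params()) {
  rows <- list(); evid <- list()
  for (rule in rules) {
    if (rule$polarity != s$polarity) next
    req <- do.call(rbind, Filter(Negate(is.null),
      lapply(rule$required, .match_item, s = s, params = params)))
    n_req <- if (is.null(req)) 0L else nrow(req)
    if (n_req < rule$min_required) next
    sup <- do.call(rbind, Filter(Negate(is.null),
      lapply(rule$supporting, .match_item, s = s, params = params)))
    n_sup <- if (is.null(sup)) 0L else nrow(sup)
    ev <- rbind(
      if (!is.null(req)) cbind(req, role = "required"),
      if (!is.null(sup)) cbind(sup, role = "supporting"))
    rows[[length(rows) + 1L]] <- data.frame(
      class_id = rule$class_id, n_required = n_req, n_supporting = n_sup,
      matched_intensity = sum(ev$intensity), stringsAsFactors = FALSE)
    evid[[length(evid) + 1L]] <- ev
  }
  if (!length(rows)) {
    out <- data.frame(class_id = character(0), n_required = integer(0),
                      n_supporting = integer(0), matched_intensity = numeric(0))
    attr(out, "evidence") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  prio <- match(out$class_id, params$class_priority)
  ord <- order(-out$n_required, -out$n_supporting, -out$matched_intensity, prio)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "evidence") <- evid[ord]
  out
}
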