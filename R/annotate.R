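# Chain composition algebra, LIPID MAPS species-level shorthand, and the
# annotation cascade: class detection -> precursor formula -> chain
# inference -> shorthand.
#
# A chain set is a data frame with columns carbons, db, oxy, linkage
# (one row per chain; linkage "acyl", "ether", "sphingoid" or "sum").
# "sum" marks an unresolved sum composition (single row).

.chain_row <- function(carbons, db, oxy = 0L, linkage = "acyl") {
  data.frame(carbons = as.integer(carbons), db = as.integer(db),
             oxy = as.integer(oxy), linkage = linkage,
             stringsAsFactors = FALSE)
}

# Element contribution of one chain to the neutral molecule of a
# glycerophospholipid (ester bond for acyl, ether bond for alkyl chains).
.chain_contribution <- function(carbons, db, oxy, linkage) {
  if (linkage == "acyl") {
    c(C = as.integer(carbons), H = as.integer(2 * carbons - 2 - 2 * db),
      O = as.integer(1 + oxy))
  } else if (linkage == "ether") {
    out <- c(C = as.integer(carbons), H = as.integer(2 * carbons - 2 * db))
    if (oxy > 0) out <- c(out, O = as.integer(oxy))
    out
  } else {
    stop("no per-chain contribution for linkage ", linkage)
  }
}

# Collapse a chain set to total (carbons, db, oxy). Sphingoid rows carry
# their two hydroxyls implicitly (oxy = 2 at the sum level).
.chain_totals <- function(chains) {
  oxy <- chains$oxy
  oxy[chains$linkage == "sphingoid"] <- oxy[chains$linkage == "sphingoid"] + 2L
  list(carbons = sum(chains$carbons), db = sum(chains$db), oxy = sum(oxy))
}

#' Neutral molecular formula of a lipid species
#'
#' @param class_id One of `"GPI"`, `"GPG"`, `"GPE"`, `"GPA"`, `"cGPA"`,
#'   `"GPS"`, `"GPC"`, `"IPC"`, `"PG"`.
#' @param chains Chain-set data frame (columns carbons, db, oxy, linkage).
#' @return Named integer vector: the neutral molecule's element counts.
#' @export
species_formula <- function(class_id, chains) {
  if (class_id == "PG") {
    # prostaglandin-type oxylipin: free fatty acid CnH(2n-2d)O(2+k)
    tot <- .chain_totals(chains)
    return(c(C = tot$carbons, H = as.integer(2 * tot$carbons - 2 * tot$db),
             O = as.integer(2 + tot$oxy)))
  }
  if (class_id == "IPC") {
    # ceramide + inositol phosphate: C(n+6) H(2n-2d+12) N O(9+k) P
    tot <- .chain_totals(chains)
    return(c(C = as.integer(tot$carbons + 6),
             H = as.integer(2 * tot$carbons - 2 * tot$db + 12),
             N = 1L, O = as.integer(9 + tot$oxy), P = 1L))
  }
  backbone <- parse_formula(.BACKBONE[[class_id]])
  if (any(chains$linkage == "sum")) {
    stop("sum composition cannot be converted to a formula for class ", class_id,
         " without a linkage assignment")
  }
  out <- backbone
  for (i in seq_len(nrow(chains))) {
    out <- formula_add(out, .chain_contribution(
      chains$carbons[i], chains$db[i], chains$oxy[i], chains$linkage[i]))
  }
  out
}

.oxy_suffix <- function(oxy) {
  if (oxy == 0L) "" else if (oxy == 1L) ";O" else paste0(";O", oxy)
}

.chain_token <- function(carbons, db, oxy, linkage) {
  paste0(if (linkage == "ether") "O-" else "", carbons, ":", db, .oxy_suffix(oxy))
}

# Display stem per class: lyso forms get an L prefix, cyclic GPA is CPA.
.CLASS_STEM <- c(GPI = "PI", GPG = "PG", GPE = "PE", GPA = "PA",
                 GPS = "PS", GPC = "PC")

#' Species-level shorthand name for a lipid
#'
#' Produces LIPID MAPS-style shorthand: lyso glycerophospholipids as
#' `"LPI 18:0"`, ether chains as `"LPG O-14:0"`, resolved two-chain
#' species as `"PI 18:0/6:1;O2"`, ceramide phosphoinositols as
#' `"IPC (d18:1/16:0)"` when the sphingoid/acyl split is known and
#' `"IPC 34:3;O2"` otherwise, and prostaglandin-type oxylipins as
#' `"FA 20:4;O3"`.
#'
#' @inheritParams species_formula
#' @return A single character string.
#' @export
shorthand_name <- function(class_id, chains) {
  if (class_id == "PG") {
    tot <- .chain_totals(chains)
    return(paste0("FA ", tot$carbons, ":", tot$db, .oxy_suffix(tot$oxy)))
  }
  if (class_id == "IPC") {
    if (nrow(chains) == 2L && "sphingoid" %in% chains$linkage) {
      sph <- chains[chains$linkage == "sphingoid", ][1L, ]
      acy <- chains[chains$linkage != "sphingoid", ][1L, ]
      return(paste0("IPC (d", sph$carbons, ":", sph$db, "/",
                    acy$carbons, ":", acy$db, .oxy_suffix(acy$oxy), ")"))
    }
    tot <- .chain_totals(chains)
    return(paste0("IPC ", tot$carbons, ":", tot$db, .oxy_suffix(tot$oxy)))
  }
  if (class_id == "cGPA") {
    ch <- chains[1L, ]
    return(paste0("CPA ", .chain_token(ch$carbons, ch$db, ch$oxy, ch$linkage)))
  }
  stem <- .CLASS_STEM[[class_id]]
  if (nrow(chains) == 1L) {
    ch <- chains[1L, ]
    return(paste0("L", stem, " ",
                  .chain_token(ch$carbons, ch$db, ch$oxy, ch$linkage)))
  }
  # two resolved chains: ether chain first, otherwise longer chain first
  ord <- order(chains$linkage != "ether", -chains$carbons, chains$db)
  chains <- chains[ord, ]
  paste0(stem, " ",
         .chain_token(chains$carbons[1], chains$db[1], chains$oxy[1],
                      chains$linkage[1]),
         "/",
         .chain_token(chains$carbons[2], chains$db[2], chains$oxy[2],
                      chains$linkage[2]))
}

#' Parse a species-level shorthand name
#'
#' Inverse of [shorthand_name()] over the grammar used in this package.
#'
#' @param name Shorthand string, e.g. `"LPI 18:0"`, `"PI O-18:0/6:1;O2"`,
#'   `"IPC (d18:1/16:0)"`, `"FA 20:5;O2"`, `"CPA 16:0"`.
#' @return List with `class_id` and `chains` (chain-set data frame).
#' @export
parse_shorthand <- function(name) {
  name <- trimws(name)
  m <- regexec("^([A-Za-z]+) (.+)$", name)[[1L]]
  if (m[1L] == -1L) stop("cannot parse shorthand ", sQuote(name))
  prefix <- regmatches(name, regexec("^([A-Za-z]+) ", name))[[1L]][2L]
  rest <- sub("^[A-Za-z]+ ", "", name)
  class_map <- c(LPI = "GPI", PI = "GPI", LPG = "GPG", PG = "GPG",
                 LPE = "GPE", PE = "GPE", LPA = "GPA", PA = "GPA",
                 CPA = "cGPA", LPS = "GPS", PS = "GPS",
                 LPC = "GPC", PC = "GPC", IPC = "IPC", FA = "PG")
  if (!prefix %in% names(class_map)) stop("unknown class prefix ", sQuote(prefix))
  class_id <- class_map[[prefix]]
  parse_token <- function(tok, linkage_default = "acyl") {
    ether <- startsWith(tok, "O-")
    if (ether) tok <- sub("^O-", "", tok)
    m <- regexec("^([0-9]+):([0-9]+)(;O([0-9]*))?$", tok)[[1L]]
    parts <- regmatches(tok, regexec("^([0-9]+):([0-9]+)(;O([0-9]*))?$", tok))[[1L]]
    if (!length(parts)) stop("cannot parse chain token ", sQuote(tok))
    oxy <- if (parts[4L] == "") 0L
           else if (parts[5L] == "") 1L else as.integer(parts[5L])
    .chain_row(as.integer(parts[2L]), as.integer(parts[3L]), oxy,
               if (ether) "ether" else linkage_default)
  }
  if (class_id == "IPC" && startsWith(rest, "(")) {
    inner <- sub("^\\((.*)\\)$", "\\1", rest)
    toks <- strsplit(inner, "/", fixed = TRUE)[[1L]]
    sph_tok <- sub("^d", "", toks[1L])
    sph <- parse_token(sph_tok, "sphingoid")
    sph$linkage <- "sphingoid"
    return(list(class_id = class_id,
                chains = rbind(sph, parse_token(toks[2L], "acyl"))))
  }
  toks <- strsplit(rest, "/", fixed = TRUE)[[1L]]
  chains <- do.call(rbind, lapply(toks, parse_token))
  # single-token IPC and FA names are sum compositions, not single chains
  if (class_id %in% c("IPC", "PG") && nrow(chains) == 1L) chains$linkage <- "sum"
  list(class_id = class_id, chains = chains)
}

#' Canonical sum composition of an annotation
#'
#' Collapses a chain set to `"<class> <C>:<DB>;O<k>"` at the species
#' (sum-composition) level, the granularity at which two annotations of
#' the same compound are comparable regardless of whether the chain split
#' was resolved.
#'
#' @inheritParams species_formula
#' @return A single character string, e.g. `"IPC 34:1;O2"`.
#' @export
sum_composition <- function(class_id, chains) {
  tot <- .chain_totals(chains)
  ether <- any(chains$linkage == "ether")
  paste0(.CHEM_CLASS[[class_id]], " ", if (ether) "O-" else "",
         tot$carbons, ":", tot$db, .oxy_suffix(tot$oxy))
}

#' Enumerate precursor ion formulas for a lipid class
#'
#' Enumerates the class's species template over chain bounds (total
#' carbons, double bonds, extra oxygens, and 0/1/2 ester bonds for the
#' glycerophospholipid classes), computes each candidate's adduct ion m/z,
#' and keeps candidates within the precursor tolerance, sorted by
#' absolute ppm error.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param polarity `"positive"` or `"negative"`.
#' @param class_id Lipid class id.
#' @param params An [annotation_params()] list.
#' @return Data frame: `ion_formula`, `neutral_formula`, `theoretical_mz`,
#'   `ppm`, plus template coordinates `n_ester`, `carbons`, `db`, `oxy`.
#' @export
infer_precursor_formula <- function(precursor_mz, polarity, class_id,
                                    params = annotation_params()) {
  mH <- monoisotopic_mass("H")
  mC <- 12; mO <- monoisotopic_mass("O")
  chg <- if (polarity == "positive") +1 else -1
  cb <- params$chain_carbons; db <- params$chain_db; ob <- params$chain_oxygens
  if (class_id == "IPC") {
    grid <- expand.grid(carbons = seq.int(max(cb[1L], 24L), cb[2L]),
                        db = seq.int(db[1L], db[2L]),
                        oxy = 2:4, n_ester = NA_integer_)
    h <- 2 * grid$carbons - 2 * grid$db + 12
    mass <- mC * (grid$carbons + 6) + mH * h +
      monoisotopic_mass("N") + mO * (9 + grid$oxy) + monoisotopic_mass("P")
  } else if (class_id == "PG") {
    grid <- expand.grid(carbons = 16:24, db = seq.int(db[1L], db[2L]),
                        oxy = 1:4, n_ester = NA_integer_)
    h <- 2 * grid$carbons - 2 * grid$db
    mass <- mC * grid$carbons + mH * h + mO * (2 + grid$oxy)
  } else {
    backbone_mass <- monoisotopic_mass(.BACKBONE[[class_id]])
    grid <- expand.grid(carbons = seq.int(cb[1L], cb[2L]),
                        db = seq.int(db[1L], db[2L]),
                        oxy = seq.int(ob[1L], ob[2L]),
                        n_ester = 0:2)
    h <- 2 * grid$carbons - 2 * grid$n_ester - 2 * grid$db
    mass <- backbone_mass + mC * grid$carbons + mH * h +
      mO * (grid$n_ester + grid$oxy)
  }
  ok <- h > 0
  grid <- grid[ok, , drop = FALSE]; mass <- mass[ok]
  theo <- mass + chg * mH - sign(chg) * .ELECTRON_MASS
  ppm <- ppm_error(precursor_mz, theo)
  keep <- abs(ppm) <= params$precursor_tol_ppm
  grid <- grid[keep, , drop = FALSE]
  theo <- theo[keep]; ppm <- ppm[keep]
  if (!nrow(grid)) {
    return(data.frame(ion_formula = character(0), neutral_formula = character(0),
                      theoretical_mz = numeric(0), ppm = numeric(0),
                      n_ester = integer(0), carbons = integer(0),
                      db = integer(0), oxy = integer(0)))
  }
  neutral <- character(nrow(grid)); ionf <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- if (class_id == "IPC") {
      species_formula("IPC", .chain_row(grid$carbons[i], grid$db[i],
                                        grid$oxy[i], "sum"))
    } else if (class_id == "PG") {
      species_formula("PG", .chain_row(grid$carbons[i], grid$db[i],
                                       grid$oxy[i], "sum"))
    } else {
      fb <- parse_formula(.BACKBONE[[class_id]])
      add <- c(C = grid$carbons[i],
               H = as.integer(2 * grid$carbons[i] - 2 * grid$n_ester[i] -
                                2 * grid$db[i]))
      o <- grid$n_ester[i] + grid$oxy[i]
      if (o > 0) add <- c(add, O = as.integer(o))
      formula_add(fb, add)
    }
    neutral[i] <- format_formula(f)
    ion <- adduct_ion(f, if (chg > 0) "[M+H]+" else "[M-H]-")
    ionf[i] <- format_formula(ion$formula)
  }
  out <- data.frame(ion_formula = ionf, neutral_formula = neutral,
                    theoretical_mz = theo, ppm = ppm,
                    n_ester = grid$n_ester, carbons = grid$carbons,
                    db = grid$db, oxy = grid$oxy, stringsAsFactors = FALSE)
  out <- out[!duplicated(out$ion_formula), , drop = FALSE]
  out[order(abs(out$ppm)), , drop = FALSE]
}

# Interpret a CHO residual (neutral molecule minus backbone) as a single
# chain. Returns a list of valid interpretations, acyl first.
.single_chain_readings <- function(res, params) {
  C <- .cnt(res, "C"); H <- .cnt(res, "H"); O <- .cnt(res, "O")
  out <- list()
  if (O >= 1) {
    d <- (2 * C - 2 - H) / 2
    k <- O - 1L
    if (d == floor(d) && d >= params$chain_db[1L] && d <= params$chain_db[2L] &&
        k >= 0 && k <= params$chain_oxygens[2L]) {
      out[[length(out) + 1L]] <- .chain_row(C, d, k, "acyl")
    }
  }
  d <- (2 * C - H) / 2
  if (d == floor(d) && d >= params$chain_db[1L] && d <= params$chain_db[2L] &&
      O >= 0 && O <= params$chain_oxygens[2L]) {
    out[[length(out) + 1L]] <- .chain_row(C, d, O, "ether")
  }
  out
}

.res_counts <- function(f) {
  bad <- setdiff(names(f), c("C", "H", "O"))
  if (length(bad)) return(NULL)
  c(C = .cnt(f, "C"), H = .cnt(f, "H"), O = .cnt(f, "O"))
}

# count of one element in a named formula vector (0 when absent)
.cnt <- function(f, el) if (el %in% names(f)) as.integer(f[[el]]) else 0L

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1L])) b else a

#' Infer the chain composition of an annotated precursor
#'
#' Given a class and a fixed neutral precursor formula, searches the
#' spectrum for chain-diagnostic evidence — carboxylate anions and
#' class-specific chain-release losses in negative mode, chain-release
#' loss fragments (and, for IPC, the combined water + inositol phosphate +
#' fatty acyl ketene loss) in positive mode — and derives the chain set
#' from the residual formula. Without evidence the composition falls back
#' to arithmetic on (precursor minus backbone); the confidence drops to
#' `"class"` when that arithmetic is ambiguous between an acyl and an
#' ether reading.
#'
#' @param s An [ms2_spectrum].
#' @param class_id Lipid class id.
#' @param neutral_formula Neutral molecule formula (string or counts).
#' @param params An [annotation_params()] list.
#' @param rules Rule list from [builtin_rules()] (source of the class's
#'   chain-release losses).
#' @return List with `chains` (chain-set data frame), `confidence`
#'   (`"species"` or `"class"`) and `evidence` (data frame of matched
#'   chain-diagnostic peaks), or `NULL` when the residual is not
#'   interpretable as a chain.
#' @export
infer_chain <- function(s, class_id, neutral_formula,
                        params = annotation_params(), rules = builtin_rules()) {
  if (is.character(neutral_formula)) neutral_formula <- parse_formula(neutral_formula)
  ev <- data.frame(kind = character(0), formula = character(0),
                   expected_mz = numeric(0), matched_mz = numeric(0),
                   intensity = numeric(0), ppm = numeric(0),
                   stringsAsFactors = FALSE)
  if (class_id == "PG") {
    C <- .cnt(neutral_formula, "C")
    H <- .cnt(neutral_formula, "H")
    O <- .cnt(neutral_formula, "O")
    d <- (2 * C - H) / 2; k <- O - 2L
    if (d != floor(d) || d < 0 || k < 0) return(NULL)
    return(list(chains = .chain_row(C, d, k, "sum"),
                confidence = "species", evidence = ev))
  }
  if (class_id == "IPC") {
    C <- .cnt(neutral_formula, "C")
    H <- .cnt(neutral_formula, "H")
    O <- .cnt(neutral_formula, "O")
    n <- C - 6L; d <- (2 * n + 12 - H) / 2; k <- O - 9L
    if (d != floor(d) || d < 0 || k < 2) return(NULL)
    if (s$polarity == "positive") {
      # scan fatty acyl ketene candidates in the combined loss
      base_loss <- monoisotopic_mass("H2O") + monoisotopic_mass("C6H13O9P")
      best <- NULL
      for (x in 10:26) {
        for (y in 0:6) {
          hk <- 2 * x - 2 - 2 * y
          if (hk <= 0) next
          ket <- 12 * x + monoisotopic_mass("H") * hk + monoisotopic_mass("O")
          target <- s$precursor_mz - base_loss - ket
          if (target <= 50) next
          i <- .find_peak(s, target, params)
          if (is.na(i)) next
          nb <- n - x; db <- d - y
          if (nb < 12 || nb > 24 || db < 0 || db > 3 || k != 2L) next
          cand <- list(x = x, y = y, nb = nb, db = db,
                       intensity = s$intensity[i], mz = s$mz[i],
                       target = target)
          if (is.null(best) || cand$intensity > best$intensity) best <- cand
        }
      }
      if (!is.null(best)) {
        chains <- rbind(.chain_row(best$nb, best$db, 0L, "sphingoid"),
                        .chain_row(best$x, best$y, 0L, "acyl"))
        ev <- data.frame(kind = "chain_loss",
                         formula = paste0("H2O+C6H13O9P+ketene(",
                                          best$x, ":", best$y, ")"),
                         expected_mz = best$target, matched_mz = best$mz,
                         intensity = best$intensity,
                         ppm = ppm_error(best$mz, best$target),
                         stringsAsFactors = FALSE)
        return(list(chains = chains, confidence = "species", evidence = ev))
      }
    }
    return(list(chains = .chain_row(n, d, k, "sum"),
                confidence = "species", evidence = ev))
  }
  # glycerophospholipid classes: residual = neutral - backbone
  backbone <- parse_formula(.BACKBONE[[class_id]])
  res_f <- tryCatch(formula_subtract(neutral_formula, backbone),
                    error = function(e) NULL)
  if (is.null(res_f)) return(NULL)
  res <- .res_counts(res_f)
  if (is.null(res)) return(NULL)
  singles <- .single_chain_readings(res, params)
  splits <- list()
  if (s$polarity == "negative") {
    # generic carboxylate-anion scan over the chain grid
    for (x in 2:min(res[["C"]], 30L)) {
      for (y in 0:8) {
        hh <- 2 * x - 1 - 2 * y
        if (hh < 1) next
        for (z in 0:4) {
          mzt <- ion_mz(c(C = x, H = hh, O = 2L + z), -1L)
          if (mzt >= s$precursor_mz - 1) next
          i <- .find_peak(s, mzt, params)
          if (is.na(i)) next
          contrib <- c(C = x, H = hh - 1L, O = 1L + z)  # ester-bound form
          comp <- tryCatch(formula_subtract(res, contrib), error = function(e) NULL)
          if (is.null(comp)) next
          ev_row <- data.frame(kind = "carboxylate",
                               formula = format_formula(c(C = x, H = hh, O = 2L + z)),
                               expected_mz = mzt, matched_mz = s$mz[i],
                               intensity = s$intensity[i],
                               ppm = ppm_error(s$mz[i], mzt),
                               stringsAsFactors = FALSE)
          if (length(comp) == 0L) {
            # the carboxylate accounts for the whole residual: lyso species
            splits[[length(splits) + 1L]] <- list(
              chains = .chain_row(x, y, z, "acyl"), ev = ev_row,
              intensity = s$intensity[i])
          } else {
            comp_counts <- .res_counts(comp)
            if (is.null(comp_counts)) next
            other <- .single_chain_readings(comp_counts, params)
            if (!length(other)) next
            ch2 <- other[[1L]]
            if (ch2$carbons < 2L) next
            splits[[length(splits) + 1L]] <- list(
              chains = rbind(.chain_row(x, y, z, "acyl"), ch2), ev = ev_row,
              intensity = s$intensity[i])
          }
        }
      }
    }
  }
  # class-specific chain-release losses (primarily positive mode evidence)
  release_ev <- NULL
  rule <- NULL
  for (r in rules) {
    if (r$class_id == class_id && r$polarity == s$polarity) rule <- r
  }
  if (!is.null(rule)) {
    for (item in rule$chain_release) {
      target <- s$precursor_mz - item$mass
      if (target <= 0) next
      i <- .find_peak(s, target, params)
      if (!is.na(i)) {
        release_ev <- rbind(release_ev, data.frame(
          kind = "chain_loss", formula = item$formula,
          expected_mz = target, matched_mz = s$mz[i],
          intensity = s$intensity[i], ppm = ppm_error(s$mz[i], target),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (length(splits)) {
    # prefer the split supported by the most intense carboxylate; break
    # remaining ties canonically (fewer chains, then longer first chain)
    ord <- order(-vapply(splits, function(sp) sp$intensity, numeric(1)),
                 vapply(splits, function(sp) nrow(sp$chains), integer(1)),
                 -vapply(splits, function(sp) max(sp$chains$carbons), integer(1)))
    pick <- splits[[ord[1L]]]
    ev <- do.call(rbind, c(list(pick$ev), if (!is.null(release_ev)) list(release_ev)))
    return(list(chains = pick$chains, confidence = "species", evidence = ev))
  }
  if (!length(singles)) return(NULL)
  pick <- singles[[order(vapply(singles, function(ch) ch$oxy, integer(1)),
                         vapply(singles, function(ch) ch$linkage != "acyl",
                                logical(1)))[1L]]]
  confidence <- if (length(singles) == 1L || !is.null(release_ev)) "species" else "class"
  if (!is.null(release_ev)) ev <- release_ev
  list(chains = pick, confidence = confidence, evidence = ev)
}

#' Annotate one MS2 spectrum
#'
#' Runs the full dereplication cascade: [detect_class()] ranks class
#' candidates from diagnostic ions and neutral losses; for each candidate
#' in rank order [infer_precursor_formula()] looks for a species formula
#' within the precursor tolerance and [infer_chain()] interprets the chain
#' composition; the first candidate that passes all three stages yields
#' the annotation.
#'
#' @param s An [ms2_spectrum].
#' @param rules Rule list from [builtin_rules()].
#' @param params An [annotation_params()] list.
#' @return A list of class `lipid_annotation` (fields: feature_id,
#'   class_id, chemical_class, shorthand, sum_composition, ion_formula,
#'   neutral_formula, theoretical_mz, precursor_ppm, confidence, evidence,
#'   chain evidence), or `NULL` when no class passes.
#' @export
annotate_spectrum <- function(s, rules = builtin_rules(),
                              params = annotation_params()) {
  if (!length(s$mz)) return(NULL)
  cands <- detect_class(s, rules, params)
  if (!nrow(cands)) return(NULL)
  evid <- attr(cands, "evidence")
  for (ci in seq_len(nrow(cands))) {
    class_id <- cands$class_id[ci]
    forms <- infer_precursor_formula(s$precursor_mz, s$polarity, class_id, params)
    if (!nrow(forms)) next
    for (fi in seq_len(min(nrow(forms), 3L))) {
      chain <- infer_chain(s, class_id, forms$neutral_formula[fi], params, rules)
      if (is.null(chain)) next
      ann <- structure(list(
        feature_id = s$feature_id,
        polarity = s$polarity,
        class_id = class_id,
        chemical_class = .CHEM_CLASS[[class_id]],
        shorthand = shorthand_name(class_id, chain$chains),
        sum_composition = sum_composition(class_id, chain$chains),
        chains = chain$chains,
        ion_formula = forms$ion_formula[fi],
        neutral_formula = forms$neutral_formula[fi],
        theoretical_mz = forms$theoretical_mz[fi],
        precursor_mz = s$precursor_mz,
        precursor_ppm = forms$ppm[fi],
        confidence = chain$confidence,
        class_evidence = evid[[ci]],
        chain_evidence = chain$evidence
      ), class = "lipid_annotation")
      stopifnot(abs(ann$precursor_ppm) <= params$precursor_tol_ppm)
      return(ann)
    }
  }
  NULL
}

#' @export
print.lipid_annotation <- function(x, ...) {
  cat(sprintf("%s  [%s, %s mode]\n", x$shorthand, x$chemical_class, x$polarity))
  cat(sprintf("  ion %s at m/z %.4f (observed %.4f, %+.2f ppm), confidence: %s\n",
              x$ion_formula, x$theoretical_mz, x$precursor_mz,
              x$precursor_ppm, x$confidence))
  cat(sprintf("  evidence: %d class item(s), %d chain item(s)\n",
              nrow(x$class_evidence), nrow(x$chain_evidence)))
  invisible(x)
}

#' Annotate a list of spectra
#'
#' @param spectra List of [ms2_spectrum] objects.
#' @inheritParams annotate_spectrum
#' @return Data frame with one row per annotated spectrum (feature_id,
#'   polarity, class_id, chemical_class, shorthand, sum_composition,
#'   ion_formula, precursor_ppm, confidence, n_evidence); unannotated
#'   spectra are absent. The full `lipid_annotation` objects are attached
#'   as attribute `"annotations"`, named by feature id.
#' @export
annotate_spectra <- function(spectra, rules = builtin_rules(),
                             params = annotation_params()) {
  anns <- list()
  rows <- list()
  for (s in spectra) {
    a <- annotate_spectrum(s, rules, params)
    if (is.null(a)) next
    anns[[a$feature_id]] <- a
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = a$feature_id, polarity = a$polarity,
      class_id = a$class_id, chemical_class = a$chemical_class,
      shorthand = a$shorthand, sum_composition = a$sum_composition,
      ion_formula = a$ion_formula, precursor_ppm = a$precursor_ppm,
      confidence = a$confidence,
      n_evidence = nrow(a$class_evidence) + nrow(a$chain_evidence),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    feature_id = character(0), polarity = character(0),
    class_id = character(0), chemical_class = character(0),
    shorthand = character(0), sum_composition = character(0),
    ion_formula = character(0), precursor_ppm = numeric(0),
    confidence = character(0), n_evidence = integer(0))
  attr(out, "annotations") <- anns
  out
}
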