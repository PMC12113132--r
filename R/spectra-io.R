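# MS2 spectrum data model plus MGF / feature-quantification-table I/O.
#
# A spectrum is the unit both of networking and of rule-based annotation:
# precursor m/z, polarity, retention time (minutes) and a peak list sorted
# by ascending m/z.

#' Construct an MS2 spectrum
#'
#' @param feature_id Feature identifier (coerced to character).
#' @param precursor_mz Precursor m/z in Da (> 0).
#' @param polarity `"positive"` or `"negative"`.
#' @param rt Retention time in minutes (>= 0).
#' @param mz Numeric vector of fragment m/z values.
#' @param intensity Numeric vector of intensities (>= 0), same length.
#' @return An object of class `ms2_spectrum`. Peaks are sorted by m/z;
#'   duplicates closer than 1e-6 Da are merged by summing intensities.
#' @export
ms2_spectrum <- function(feature_id, precursor_mz, polarity, rt, mz, intensity) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(length(mz) == length(intensity))
  if (!is.finite(precursor_mz) || precursor_mz <= 0) {
    stop("precursor_mz must be a positive finite number")
  }
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
      stop("peak m/z and intensity must be finite")
    }
    if (any(mz <= 0)) stop("peak m/z must be positive")
    if (any(intensity < 0)) stop("peak intensity must be non-negative")
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (length(mz) > 1L) {
      grp <- cumsum(c(TRUE, diff(mz) > 1e-6))
      if (max(grp) < length(mz)) {
        intensity <- as.numeric(tapply(intensity, grp, sum))
        mz <- as.numeric(tapply(mz, grp, function(x) x[1L]))
      }
    }
  }
  structure(
    list(feature_id = as.character(feature_id),
         precursor_mz = as.numeric(precursor_mz),
         polarity = polarity,
         rt = as.numeric(rt),
         mz = as.numeric(mz),
         intensity = as.numeric(intensity)),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("MS2 spectrum [feature %s] %s mode\n", x$feature_id, x$polarity))
  cat(sprintf("  precursor m/z %.4f, RT %.2f min, %d peaks\n",
              x$precursor_mz, x$rt, length(x$mz)))
  invisible(x)
}

n_peaks <- function(s) length(s$mz)

base_peak_intensity <- function(s) if (length(s$intensity)) max(s$intensity) else 0

#' Read an MGF file of MS2 spectra
#'
#' Supports the MGF dialect produced by feature-based workflows:
#' `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE` (`1+`/`1-`) or
#' `ION_MODE` (`positive`/`negative`), `RTINSECONDS` or `RTINMINUTES`, and
#' `FEATURE_ID` or `SCANS`. Retention time is converted to minutes.
#'
#' @param path Path to an MGF file.
#' @return List of [ms2_spectrum] objects. A block with an empty peak list
#'   is retained (and a warning raised); a block with no `PEPMASS` is an
#'   error naming the block index.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends)) stop("unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(begins))
  empties <- 0L
  for (i in seq_along(begins)) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_kv <- grepl("^[A-Za-z_]+=", block)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- keys
    if (!"PEPMASS" %in% keys) stop("MGF block ", i, " has no PEPMASS")
    pepmass <- as.numeric(strsplit(trimws(vals[["PEPMASS"]]), "[[:space:]]+")[[1L]][1L])
    polarity <- NA_character_
    if ("CHARGE" %in% keys) {
      ch <- trimws(vals[["CHARGE"]])
      if (grepl("-", ch, fixed = TRUE)) polarity <- "negative"
      else polarity <- "positive"
    }
    if (is.na(polarity) && "ION_MODE" %in% keys) {
      im <- tolower(trimws(vals[["ION_MODE"]]))
      polarity <- if (startsWith(im, "n")) "negative" else "positive"
    }
    if (is.na(polarity)) stop("MGF block ", i, " has neither CHARGE nor ION_MODE")
    rt <- 0
    if ("RTINSECONDS" %in% keys) rt <- as.numeric(vals[["RTINSECONDS"]]) / 60
    if ("RTINMINUTES" %in% keys) rt <- as.numeric(vals[["RTINMINUTES"]])
    fid <- if ("FEATURE_ID" %in% keys) vals[["FEATURE_ID"]]
           else if ("SCANS" %in% keys) vals[["SCANS"]]
           else as.character(i)
    peak_lines <- block[!is_kv]
    mz <- numeric(0); inten <- numeric(0)
    if (length(peak_lines)) {
      mat <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[[:space:]]+"),
                                   function(x) as.numeric(x[1:2])))
      mz <- mat[, 1L]; inten <- mat[, 2L]
      if (any(is.na(mz)) || any(is.na(inten))) {
        stop("MGF block ", i, ": malformed peak line")
      }
    } else {
      empties <- empties + 1L
    }
    out[[i]] <- ms2_spectrum(fid, pepmass, polarity, rt, mz, inten)
  }
  if (empties > 0L) {
    warning(empties, " MGF block(s) had an empty peak list (retained)")
  }
  out
}

#' Write MS2 spectra to an MGF file
#'
#' Inverse of [read_mgf()] on its canonical dialect: m/z written with 6
#' decimals, intensities with 4, retention time as `RTINSECONDS`.
#'
#' @param spectra List of [ms2_spectrum] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wb")  # binary: stable bytes across platforms
  on.exit(close(con))
  for (s in spectra) {
    lines <- c(
      "BEGIN IONS",
      paste0("FEATURE_ID=", s$feature_id),
      paste0("PEPMASS=", formatC(s$precursor_mz, format = "f", digits = 6)),
      paste0("CHARGE=", if (s$polarity == "positive") "1+" else "1-"),
      paste0("RTINSECONDS=", formatC(s$rt * 60, format = "f", digits = 3)),
      if (length(s$mz)) paste(formatC(s$mz, format = "f", digits = 6),
                              formatC(s$intensity, format = "f", digits = 4)),
      "END IONS",
      ""
    )
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a feature quantification table
#'
#' Reads the FBMN-style CSV export: columns `row ID`, `row m/z`,
#' `row retention time`, then one `<sample> Peak area` column per sample.
#'
#' @param path Path to a CSV file.
#' @return A data frame with columns `feature_id` (character),
#'   `precursor_mz`, `rt`, and one numeric area column per sample (named by
#'   sample). Attribute `samples` carries the sample names in file order.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cols <- names(df)
  need <- c("row ID", "row m/z", "row retention time")
  if (!all(need %in% cols)) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  area_cols <- grep(" Peak area$", cols, value = TRUE)
  if (!length(area_cols)) stop("feature table has no '<sample> Peak area' columns")
  samples <- sub(" Peak area$", "", area_cols)
  out <- data.frame(
    feature_id = as.character(df[["row ID"]]),
    precursor_mz = as.numeric(df[["row m/z"]]),
    rt = as.numeric(df[["row retention time"]]),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(samples)) out[[samples[i]]] <- as.numeric(df[[area_cols[i]]])
  if (anyDuplicated(out$feature_id)) {
    stop("duplicate feature id(s) in feature table: ",
         paste(unique(out$feature_id[duplicated(out$feature_id)]), collapse = ", "))
  }
  areas <- as.matrix(out[samples])
  if (any(areas < 0)) stop("negative peak area in feature table")
  if (any(rowSums(areas) == 0)) {
    stop("feature(s) with all-zero areas: ",
         paste(out$feature_id[rowSums(areas) == 0], collapse = ", "))
  }
  attr(out, "samples") <- samples
  out
}

#' Write a feature quantification table
#'
#' @param features Data frame as returned by [read_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  samples <- attr(features, "samples")
  if (is.null(samples)) {
    samples <- setdiff(names(features), c("feature_id", "precursor_mz", "rt"))
  }
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    `row ID` = features$feature_id,
    `row m/z` = formatC(features$precursor_mz, format = "f", digits = 6),
    `row retention time` = formatC(features$rt, format = "f", digits = 3))
  for (s in samples) {
    out[[paste(s, "Peak area")]] <- formatC(features[[s]], format = "f", digits = 4)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Join spectra to feature records by feature id
#'
#' Pairing is by id only (the FBMN export guarantees shared ids); unmatched
#' items on either side are reported with warnings, not errors.
#'
#' @param spectra List of [ms2_spectrum] objects.
#' @param features Data frame from [read_feature_table()].
#' @return A list with `spectra` (the matched spectra), `features` (matched
#'   rows, same order), `unmatched_spectra` and `unmatched_features`
#'   (character ids).
#' @export
link_features <- function(spectra, features) {
  sids <- vapply(spectra, function(s) s$feature_id, character(1))
  if (anyDuplicated(sids)) stop("duplicate feature ids among spectra")
  idx <- match(sids, features$feature_id)
  unmatched_s <- sids[is.na(idx)]
  unmatched_f <- setdiff(features$feature_id, sids)
  if (length(unmatched_s)) {
    warning(length(unmatched_s), " spectrum/spectra without feature record")
  }
  if (length(unmatched_f)) {
    warning(length(unmatched_f), " feature record(s) without spectrum")
  }
  keep <- !is.na(idx)
  matched <- features[idx[keep], , drop = FALSE]
  attr(matched, "samples") <- attr(features, "samples")
  list(spectra = spectra[keep],
       features = matched,
       unmatched_spectra = unmatched_s,
       unmatched_features = unmatched_f)
}
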