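# Modified-cosine spectral similarity and molecular network construction.
#
# The similarity is the GNPS-style modified cosine: peaks match either at
# equal m/z or offset by the precursor mass difference; matched pairs form a
# one-to-one assignment maximizing the summed product of L2-normalized
# square-root intensities. Network topology is then constrained by the
# FBMN defaults (top-K mutual neighbors, bounded component size).

#' Molecular networking parameters
#'
#' Defaults are the FBMN workflow settings used throughout the package:
#' precursor tolerance 0.02 Da, fragment tolerance 0.05 Da, cosine >= 0.7,
#' >= 4 matched peaks, <= 10 neighbors per node, <= 100 nodes per
#' component; library matching requires cosine > 0.7 and >= 6 peaks.
#'
#' @param precursor_tol,fragment_tol m/z tolerances in Da.
#' @param min_cosine Minimum cosine score to keep an edge.
#' @param min_matched_peaks Minimum matched peak count to keep an edge.
#' @param max_neighbors Maximum retained neighbors per node.
#' @param max_component Maximum nodes in a connected component.
#' @param library_min_cosine,library_min_peaks Library-match thresholds.
#' @param library_precursor_tol Precursor m/z window (Da) within which a
#'   library entry is considered for matching (the library-search analog
#'   of a precursor ion mass tolerance; homologous lipids share fragment
#'   templates, so candidates are restricted to the query's precursor
#'   neighborhood).
#' @param preprocess_window,preprocess_top_k Peak filtering: keep the
#'   `top_k` most intense peaks per non-overlapping `window` Da.
#' @return A list of class `network_params`.
#' @export
network_params <- function(precursor_tol = 0.02,
                           fragment_tol = 0.05,
                           min_cosine = 0.7,
                           min_matched_peaks = 4L,
                           max_neighbors = 10L,
                           max_component = 100L,
                           library_min_cosine = 0.7,
                           library_min_peaks = 6L,
                           library_precursor_tol = 2.0,
                           preprocess_window = 50,
                           preprocess_top_k = 6L) {
  stopifnot(precursor_tol > 0, fragment_tol > 0,
            min_cosine >= 0, min_cosine <= 1,
            min_matched_peaks >= 1, max_neighbors >= 1, max_component >= 1,
            preprocess_window > 0, preprocess_top_k >= 1)
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 min_cosine = min_cosine,
                 min_matched_peaks = as.integer(min_matched_peaks),
                 max_neighbors = as.integer(max_neighbors),
                 max_component = as.integer(max_component),
                 library_min_cosine = library_min_cosine,
                 library_min_peaks = as.integer(library_min_peaks),
                 library_precursor_tol = library_precursor_tol,
                 preprocess_window = preprocess_window,
                 preprocess_top_k = as.integer(preprocess_top_k)),
            class = "network_params")
}

#' Filter and weight a spectrum for similarity scoring
#'
#' Keeps the `top_k` most intense peaks within each non-overlapping
#' `window`-Da m/z bin and replaces intensities by their square roots
#' (the weighting under which the modified cosine is computed).
#'
#' @param s An [ms2_spectrum].
#' @param window Bin width in Da.
#' @param top_k Peaks retained per bin.
#' @return The filtered [ms2_spectrum], still sorted by m/z.
#' @export
preprocess_spectrum <- function(s, window = 50, top_k = 6L) {
  stopifnot(inherits(s, "ms2_spectrum"), window > 0, top_k >= 1)
  if (!length(s$mz)) return(s)
  bin <- floor(s$mz / window)
  keep <- logical(length(s$mz))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) > top_k) {
      idx <- idx[order(s$intensity[idx], decreasing = TRUE)[seq_len(top_k)]]
    }
    keep[idx] <- TRUE
  }
  ms2_spectrum(s$feature_id, s$precursor_mz, s$polarity, s$rt,
               s$mz[keep], sqrt(s$intensity[keep]))
}

# Exact maximum-weight one-to-one assignment over candidate peak pairs.
# pairs: data.frame(i, j, w). Solved by depth-first branch and bound over
# the peaks of spectrum a (try each candidate j or skip), exact for the
# sparse candidate sets that real tolerances produce.
.max_assignment <- function(pairs) {
  if (!nrow(pairs)) return(list(score = 0, n = 0L))
  is <- sort(unique(pairs$i))
  cand <- lapply(is, function(ii) pairs[pairs$i == ii, , drop = FALSE])
  # upper bound helper: best single weight per remaining i
  best_per_i <- vapply(cand, function(df) max(df$w), numeric(1))
  suffix_bound <- rev(cumsum(rev(best_per_i)))
  best <- list(score = -1, n = 0L)
  used <- new.env(parent = emptyenv())
  recurse <- function(k, score, n) {
    if (k > length(cand)) {
      if (score > best$score + 1e-15) best <<- list(score = score, n = n)
      return(invisible(NULL))
    }
    if (score + suffix_bound[k] <= best$score + 1e-15) return(invisible(NULL))
    df <- cand[[k]]
    ord <- order(df$w, decreasing = TRUE)
    for (r in ord) {
      j <- as.character(df$j[r])
      if (is.null(used[[j]])) {
        used[[j]] <- TRUE
        recurse(k + 1L, score + df$w[r], n + 1L)
        rm(list = j, envir = used)
      }
    }
    recurse(k + 1L, score, n)  # leave peak i unmatched
  }
  recurse(1L, 0, 0L)
  best
}

#' Modified cosine similarity between two spectra
#'
#' Peaks of `a` match peaks of `b` either directly (|dm/z| <= `fragment_tol`)
#' or shifted by the precursor mass difference. The score is the maximum,
#' over one-to-one peak assignments, of the summed products of per-spectrum
#' L2-normalized peak weights; spectra are expected to be preprocessed
#' (see [preprocess_spectrum()]), whose square-root weighting this function
#' does not re-apply.
#'
#' @param a,b [ms2_spectrum] objects of the same polarity.
#' @param fragment_tol Fragment m/z tolerance in Da.
#' @param precursor_tol Precursor m/z tolerance in Da (two precursors closer
#'   than this are treated as equal, i.e. no shifted matching is added).
#' @return List with `score` in \[0, 1\] and `n_matched`.
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.05, precursor_tol = 0.02) {
  stopifnot(inherits(a, "ms2_spectrum"), inherits(b, "ms2_spectrum"))
  if (a$polarity != b$polarity) {
    stop("modified cosine requires spectra of the same polarity")
  }
  na <- length(a$mz); nb <- length(b$mz)
  if (na == 0L || nb == 0L) return(list(score = 0, n_matched = 0L))
  wa <- a$intensity / sqrt(sum(a$intensity^2))
  wb <- b$intensity / sqrt(sum(b$intensity^2))
  shift <- a$precursor_mz - b$precursor_mz
  use_shift <- abs(shift) > precursor_tol
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(na)) {
    d <- abs(a$mz[i] - b$mz)
    hit <- d <= fragment_tol
    if (use_shift) hit <- hit | (abs(a$mz[i] - b$mz - shift) <= fragment_tol)
    js <- which(hit)
    ii <- c(ii, rep.int(i, length(js))); jj <- c(jj, js)
  }
  if (!length(ii)) return(list(score = 0, n_matched = 0L))
  pairs <- data.frame(i = ii, j = jj, w = wa[ii] * wb[jj])
  res <- .max_assignment(pairs)
  list(score = min(res$score, 1), n_matched = res$n)
}

#' Build a molecular network from MS2 spectra
#'
#' Scores all spectrum pairs of one polarity with the modified cosine,
#' keeps edges with cosine >= `min_cosine` and matched peaks >=
#' `min_matched_peaks`, and applies the topology constraints of
#' [enforce_topology()]. Spectra of mixed polarity are rejected: positive
#' and negative data form separate networks.
#'
#' @param spectra List of [ms2_spectrum] objects (single polarity).
#' @param params A [network_params()] list.
#' @param preprocess Apply [preprocess_spectrum()] before scoring
#'   (default `TRUE`).
#' @return An object of class `molecular_network`: list with `nodes`
#'   (data frame: feature_id, precursor_mz, rt, polarity, n_peaks), `edges`
#'   (data frame: node_a, node_b, cosine, n_matched, delta_mz) and `params`.
#' @export
build_network <- function(spectra, params = network_params(), preprocess = TRUE) {
  stopifnot(length(spectra) >= 1)
  pols <- unique(vapply(spectra, function(s) s$polarity, character(1)))
  if (length(pols) > 1L) {
    stop("spectra of mixed polarity; build one network per polarity")
  }
  proc <- if (preprocess) {
    lapply(spectra, preprocess_spectrum,
           window = params$preprocess_window, top_k = params$preprocess_top_k)
  } else spectra
  ids <- vapply(spectra, function(s) s$feature_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate feature ids among spectra")
  nodes <- data.frame(
    feature_id = ids,
    precursor_mz = vapply(spectra, function(s) s$precursor_mz, numeric(1)),
    rt = vapply(spectra, function(s) s$rt, numeric(1)),
    polarity = pols,
    n_peaks = vapply(spectra, n_peaks, integer(1)),
    stringsAsFactors = FALSE
  )
  n <- length(proc)
  ea <- character(0); eb <- character(0)
  ec <- numeric(0); em <- integer(0); ed <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        r <- modified_cosine(proc[[i]], proc[[j]],
                             fragment_tol = params$fragment_tol,
                             precursor_tol = params$precursor_tol)
        if (r$score >= params$min_cosine && r$n_matched >= params$min_matched_peaks) {
          ea <- c(ea, ids[i]); eb <- c(eb, ids[j])
          ec <- c(ec, r$score); em <- c(em, r$n_matched)
          ed <- c(ed, spectra[[i]]$precursor_mz - spectra[[j]]$precursor_mz)
        }
      }
    }
  }
  edges <- data.frame(node_a = ea, node_b = eb, cosine = ec,
                      n_matched = em, delta_mz = ed, stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges, params = params),
                   class = "molecular_network")
  enforce_topology(net, params$max_neighbors, params$max_component)
}

#' Enforce FBMN topology constraints on a network
#'
#' First the mutual top-K rule: an edge survives only if each endpoint
#' ranks the other within its top `max_neighbors` by cosine (ties broken by
#' the partner id, ascending). Then oversized connected components are
#' split by repeatedly removing their lowest-cosine edge (ties broken by
#' the lexicographically smallest `(node_a, node_b)` pair) until every
#' component has at most `max_component` nodes.
#'
#' @param net A `molecular_network`.
#' @param max_neighbors,max_component Topology bounds.
#' @return The constrained `molecular_network`.
#' @export
enforce_topology <- function(net, max_neighbors = 10L, max_component = 100L) {
  edges <- net$edges
  if (nrow(edges)) {
    # rank of each edge from the perspective of each endpoint
    keep <- rep(TRUE, nrow(edges))
    for (v in unique(c(edges$node_a, edges$node_b))) {
      inc <- which(edges$node_a == v | edges$node_b == v)
      if (length(inc) <= max_neighbors) next
      partner <- ifelse(edges$node_a[inc] == v, edges$node_b[inc], edges$node_a[inc])
      ord <- inc[order(-edges$cosine[inc], partner)]
      drop <- ord[-seq_len(max_neighbors)]
      keep[drop] <- FALSE
    }
    edges <- edges[keep, , drop = FALSE]
  }
  # component-size constraint
  repeat {
    if (!nrow(edges)) break
    g <- igraph::graph_from_data_frame(
      edges[, c("node_a", "node_b")], directed = FALSE,
      vertices = data.frame(name = net$nodes$feature_id))
    comp <- igraph::components(g)
    big <- which(comp$csize > max_component)
    if (!length(big)) break
    # lowest-cosine edge within the first oversized component
    cid <- big[1L]
    members <- names(comp$membership)[comp$membership == cid]
    in_comp <- which(edges$node_a %in% members & edges$node_b %in% members)
    ord <- in_comp[order(edges$cosine[in_comp], edges$node_a[in_comp],
                         edges$node_b[in_comp])]
    edges <- edges[-ord[1L], , drop = FALSE]
  }
  rownames(edges) <- NULL
  net$edges <- edges
  net
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("Molecular network (%s mode): %d nodes, %d edges\n",
              x$nodes$polarity[1] %||% "?", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
summary.molecular_network <- function(object, ...) {
  g <- as_igraph(object)
  comp <- igraph::components(g)
  cat(sprintf("Molecular network: %d nodes, %d edges, %d components\n",
              nrow(object$nodes), nrow(object$edges), comp$no))
  if (nrow(object$edges)) {
    cat(sprintf("  cosine: min %.3f, median %.3f, max %.3f\n",
                min(object$edges$cosine), stats::median(object$edges$cosine),
                max(object$edges$cosine)))
    cat(sprintf("  max degree %d, max component size %d\n",
                max(igraph::degree(g)), max(comp$csize)))
  }
  invisible(object)
}

#' @export
plot.molecular_network <- function(x, ...) {
  plot(as_igraph(x), vertex.size = 6, vertex.label.cex = 0.6, ...)
}

# igraph view of a molecular_network (node/edge attributes attached).
as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    if (nrow(net$edges)) net$edges else
      data.frame(node_a = character(0), node_b = character(0)),
    directed = FALSE,
    vertices = net$nodes
  )
}

#' Match a spectrum against an annotated spectral library
#'
#' @param s Query [ms2_spectrum].
#' @param library List of [ms2_spectrum] objects each carrying a `name`
#'   element (the annotation).
#' @param params A [network_params()] list; matches require cosine >
#'   `library_min_cosine` and matched peaks >= `library_min_peaks`.
#' @return Data frame of matches (name, cosine, n_matched, delta_mz),
#'   sorted by cosine descending; zero rows if nothing passes.
#' @export
match_library <- function(s, library, params = network_params()) {
  q <- preprocess_spectrum(s, params$preprocess_window, params$preprocess_top_k)
  rows <- list()
  for (entry in library) {
    if (entry$polarity != s$polarity) next
    if (abs(entry$precursor_mz - s$precursor_mz) > params$library_precursor_tol) next
    e <- preprocess_spectrum(entry, params$preprocess_window, params$preprocess_top_k)
    r <- modified_cosine(q, e, fragment_tol = params$fragment_tol,
                         precursor_tol = params$precursor_tol)
    if (r$score > params$library_min_cosine && r$n_matched >= params$library_min_peaks) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = entry$name %||% entry$feature_id,
        cosine = r$score, n_matched = r$n_matched,
        delta_mz = s$precursor_mz - entry$precursor_mz,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), cosine = numeric(0),
               n_matched = integer(0), delta_mz = numeric(0))
  out[order(-out$cosine), , drop = FALSE]
}

#' Export a molecular network to GraphML and CSV tables
#'
#' Node attributes carry precursor m/z, RT, annotation class and shorthand
#' (when provided), per-extract abundance proportions and total area; edge
#' attributes carry cosine, matched peak count and precursor delta.
#'
#' @param net A `molecular_network`.
#' @param file GraphML output path.
#' @param annotations Optional annotation data frame (from
#'   [annotate_spectra()]) joined by `feature_id`; unannotated nodes get
#'   class `"unknown"`.
#' @param proportions Optional data frame with `feature_id`, `total_area`
#'   and one proportion column per extract (rows sum to 1).
#' @param tables_prefix If non-`NULL`, node and edge CSVs are written to
#'   `<prefix>_nodes.csv` / `<prefix>_edges.csv`.
#' @return `file`, invisibly.
#' @export
export_graph <- function(net, file, annotations = NULL, proportions = NULL,
                         tables_prefix = NULL) {
  nodes <- net$nodes
  nodes$class <- rep("unknown", nrow(nodes))
  nodes$shorthand <- rep("", nrow(nodes))
  if (!is.null(annotations) && nrow(annotations)) {
    idx <- match(nodes$feature_id, annotations$feature_id)
    hit <- !is.na(idx)
    nodes$class[hit] <- annotations$chemical_class[idx[hit]]
    nodes$shorthand[hit] <- annotations$shorthand[idx[hit]]
  }
  if (!is.null(proportions) && nrow(proportions)) {
    idx <- match(nodes$feature_id, proportions$feature_id)
    for (col in setdiff(names(proportions), "feature_id")) {
      val <- proportions[[col]][idx]
      val[is.na(val)] <- 0
      nodes[[col]] <- val
    }
  }
  net$nodes <- nodes
  g <- as_igraph(net)
  igraph::write_graph(g, file, format = "graphml")
  if (!is.null(tables_prefix)) {
    con <- file(paste0(tables_prefix, "_nodes.csv"), "wb")
    utils::write.csv(nodes, con, row.names = FALSE, quote = FALSE, eol = "\n")
    close(con)
    con <- file(paste0(tables_prefix, "_edges.csv"), "wb")
    utils::write.csv(net$edges, con, row.names = FALSE, quote = FALSE, eol = "\n")
    close(con)
  }
  invisible(file)
}
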