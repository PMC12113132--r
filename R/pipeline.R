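# End-to-end orchestration: read (or simulate) spectra + feature areas,
# build one molecular network per ionization mode, annotate nodes with the
# lipid rule engine, attach per-extract abundance proportions, and export
# GraphML + CSV + JSON artifacts.

#' Per-extract abundance summary
#'
#' Computes per-node abundance proportions (area in each extract divided
#' by the node's total area) and aggregates them per chemical class by
#' summed area. Unannotated features are reported under class
#' `"unknown"`.
#'
#' @param annotations Annotation data frame from [annotate_spectra()]
#'   (may have zero rows).
#' @param features Feature data frame (layout of [read_feature_table()]).
#' @return List with `nodes` (feature_id, total_area, one proportion
#'   column per extract) and `classes` (class, n_nodes, per-extract summed
#'   area and per-extract proportion of the class total). Proportions sum
#'   to 1 for every node and every class.
#' @export
summarize_by_extract <- function(annotations, features) {
  samples <- attr(features, "samples")
  if (is.null(samples)) {
    samples <- setdiff(names(features), c("feature_id", "precursor_mz", "rt"))
  }
  areas <- as.matrix(features[samples])
  total <- rowSums(areas)
  zero <- total == 0
  if (any(zero)) {
    warning(sum(zero), " feature(s) with zero total area excluded from summary")
  }
  feats <- features[!zero, , drop = FALSE]
  areas <- areas[!zero, , drop = FALSE]
  total <- total[!zero]
  nodes <- data.frame(feature_id = feats$feature_id, total_area = total,
                      stringsAsFactors = FALSE)
  for (s in samples) nodes[[s]] <- areas[, s] / total
  cls <- rep("unknown", nrow(feats))
  if (nrow(annotations)) {
    idx <- match(feats$feature_id, annotations$feature_id)
    cls[!is.na(idx)] <- annotations$chemical_class[idx[!is.na(idx)]]
  }
  agg <- lapply(split(seq_len(nrow(feats)), cls), function(ii) {
    tot <- colSums(areas[ii, , drop = FALSE])
    c(n_nodes = length(ii), tot, tot / sum(tot))
  })
  classes <- data.frame(class = names(agg), stringsAsFactors = FALSE)
  m <- do.call(rbind, agg)
  classes$n_nodes <- as.integer(m[, 1L])
  for (i in seq_along(samples)) {
    classes[[paste0("area_", samples[i])]] <- m[, 1L + i]
    classes[[paste0("prop_", samples[i])]] <- m[, 1L + length(samples) + i]
  }
  classes <- classes[order(classes$class), , drop = FALSE]
  rownames(classes) <- NULL
  list(nodes = nodes, classes = classes)
}

#' Run the full dereplication pipeline
#'
#' Reads an MGF + feature quantification CSV (or takes in-memory spectra
#' and features), splits spectra by ionization mode, and for each mode
#' builds a modified-cosine molecular network, annotates every node with
#' the lipid rule engine, computes per-extract abundance proportions, and
#' writes GraphML, node/edge CSVs, an annotation CSV, an extract summary
#' CSV and a JSON run report into `out_dir`. Positive- and negative-mode
#' data are never mixed in one network.
#'
#' @param mgf,feature_csv Input paths (ignored when `spectra`/`features`
#'   are given).
#' @param spectra,features In-memory inputs (lists from the simulator or
#'   the readers).
#' @param out_dir Output directory, created if needed.
#' @param net_params A [network_params()] list.
#' @param ann_params An [annotation_params()] list.
#' @param seed Optional integer recorded in the run report (the pipeline
#'   itself is deterministic; the seed documents the simulation stream
#'   that produced synthetic inputs).
#' @return A list of class `lipidnet_run`: `networks` (per polarity),
#'   `annotations`, `summary`, `report`, `files`.
#' @export
run_pipeline <- function(mgf = NULL, feature_csv = NULL,
                         spectra = NULL, features = NULL,
                         out_dir = tempfile("lipidnet_run_"),
                         net_params = network_params(),
                         ann_params = annotation_params(),
                         seed = NULL) {
  if (is.null(spectra)) {
    if (is.null(mgf)) stop("either `mgf` or `spectra` must be given")
    if (!file.exists(mgf)) stop("MGF file not found: ", mgf)
    spectra <- read_mgf(mgf)
  }
  if (is.null(features)) {
    if (is.null(feature_csv)) stop("either `feature_csv` or `features` must be given")
    if (!file.exists(feature_csv)) stop("feature table not found: ", feature_csv)
    features <- read_feature_table(feature_csv)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  linked <- link_features(spectra, features)
  spectra <- linked$spectra
  features <- linked$features
  message(sprintf("pipeline: %d spectra linked to feature records", length(spectra)))
  rules <- builtin_rules()
  pols <- vapply(spectra, function(s) s$polarity, character(1))
  networks <- list(); files <- character(0)
  all_ann <- list()
  smry <- summarize_by_extract(
    data.frame(feature_id = character(0), chemical_class = character(0)),
    features)
  for (pol in c("positive", "negative")) {
    sub <- spectra[pols == pol]
    if (!length(sub)) {
      message("pipeline: no ", pol, " mode spectra; network skipped")
      next
    }
    net <- build_network(sub, net_params)
    ann <- annotate_spectra(sub, rules, ann_params)
    networks[[pol]] <- net
    all_ann[[pol]] <- ann
    props <- smry$nodes
    gml <- file.path(out_dir, paste0("network_", pol, ".graphml"))
    export_graph(net, gml, annotations = ann, proportions = props,
                 tables_prefix = file.path(out_dir, paste0("network_", pol)))
    files <- c(files, gml)
    message(sprintf("pipeline: %s network: %d nodes, %d edges, %d annotated",
                    pol, nrow(net$nodes), nrow(net$edges), nrow(ann)))
  }
  annotations <- do.call(rbind, c(all_ann, list(make.row.names = FALSE)))
  if (is.null(annotations)) {
    annotations <- annotate_spectra(list(), rules, ann_params)
  }
  smry <- summarize_by_extract(annotations, features)
  ann_csv <- file.path(out_dir, "annotations.csv")
  con <- file(ann_csv, "wb")
  utils::write.csv(annotations, con, row.names = FALSE, quote = TRUE, eol = "\n")
  close(con)
  sum_csv <- file.path(out_dir, "extract_summary.csv")
  con <- file(sum_csv, "wb")
  utils::write.csv(smry$classes, con, row.names = FALSE, quote = FALSE, eol = "\n")
  close(con)
  class_counts <- table(annotations$chemical_class)
  report <- list(
    n_spectra = length(spectra),
    n_features = nrow(features),
    polarities = lapply(networks, function(n)
      list(nodes = nrow(n$nodes), edges = nrow(n$edges))),
    n_annotated = nrow(annotations),
    n_unannotated = length(spectra) - nrow(annotations),
    n_classes = length(class_counts),
    class_counts = as.list(class_counts),
    seed = seed,
    params = list(network = unclass(net_params), annotation = ann_params[
      c("fragment_tol_da", "fragment_tol_ppm", "precursor_tol_ppm")])
  )
  report_json <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, report_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, ann_csv, sum_csv, report_json)
  structure(list(networks = networks, annotations = annotations,
                 summary = smry, report = report, files = files,
                 out_dir = out_dir),
            class = "lipidnet_run")
}

#' @export
print.lipidnet_run <- function(x, ...) {
  cat("lipidnet pipeline run\n")
  cat(sprintf("  %d spectra, %d annotated (%d classes)\n",
              x$report$n_spectra, x$report$n_annotated, x$report$n_classes))
  for (pol in names(x$networks)) {
    cat(sprintf("  %s network: %d nodes, %d edges\n", pol,
                nrow(x$networks[[pol]]$nodes), nrow(x$networks[[pol]]$edges)))
  }
  cat("  outputs in ", x$out_dir, "\n", sep = "")
  invisible(x)
}
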