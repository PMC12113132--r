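# Modified cosine, network construction and topology constraints.

test_that("peak preprocessing keeps top-k per window and sqrt-weights", {
  s1 <- ms2_spectrum("a", 500, "positive", 1, mz = 120.5, intensity = 49)
  p1 <- preprocess_spectrum(s1)
  expect_equal(p1$intensity, 7)
  expect_equal(p1$mz, 120.5)
  # ten peaks in one 50-Da window, top_k = 6 -> six most intense survive
  s2 <- ms2_spectrum("b", 500, "positive", 1,
                     mz = 100 + (1:10), intensity = 1:10)
  p2 <- preprocess_spectrum(s2, window = 50, top_k = 6)
  expect_length(p2$mz, 6L)
  expect_equal(sort(p2$intensity^2), as.numeric(5:10), tolerance = 1e-9)
  expect_false(is.unsorted(p2$mz))
})

test_that("modified cosine: self-similarity, disjoint spectra, symmetry", {
  fx <- reference_fixture(simulation_config(seed = 5))
  s <- preprocess_spectrum(fx$spectra[[1]])
  r <- modified_cosine(s, s)
  expect_equal(r$score, 1, tolerance = 1e-9)
  expect_identical(r$n_matched, length(s$mz))
  far <- ms2_spectrum("z", s$precursor_mz, s$polarity, 1,
                      mz = s$mz + 7.77, intensity = s$intensity)
  expect_equal(modified_cosine(s, far)$score, 0)
  opposite <- if (s$polarity == "positive") "negative" else "positive"
  expect_error(
    modified_cosine(s, ms2_spectrum("n", 400, opposite, 1, 100, 1)),
    "polarity")
  # symmetry over random pairs
  set.seed(21)
  pool <- runif(30, 100, 900)
  for (k in 1:20) {
    a <- preprocess_spectrum(random_spectrum("a", pool, sample(2:8, 1)))
    b <- preprocess_spectrum(random_spectrum("b", pool, sample(2:8, 1)))
    rab <- modified_cosine(a, b)
    rba <- modified_cosine(b, a)
    expect_equal(rab$score, rba$score, tolerance = 1e-12)
    expect_identical(rab$n_matched, rba$n_matched)
    expect_gte(rab$score, 0)
    expect_lte(rab$score, 1 + 1e-12)
  }
})

test_that("modified cosine equals the brute-force assignment oracle", {
  set.seed(33)
  pool <- runif(25, 100, 900)
  for (k in 1:60) {
    a <- preprocess_spectrum(random_spectrum("a", pool, sample(2:8, 1)))
    b <- preprocess_spectrum(random_spectrum("b", pool, sample(2:8, 1)))
    got <- modified_cosine(a, b)
    want <- oracle_modified_cosine(a, b)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
  # hand-built 4-peak pair with competing direct and shifted matches
  a <- ms2_spectrum("a", 500, "positive", 1,
                    mz = c(100, 150, 200, 250), intensity = c(4, 3, 2, 1))
  b <- ms2_spectrum("b", 510, "positive", 1,
                    mz = c(100.01, 160, 210, 260.01), intensity = c(1, 2, 3, 4))
  got <- modified_cosine(a, b)
  want <- oracle_modified_cosine(a, b)
  expect_equal(got$score, want$score, tolerance = 1e-9)
  expect_identical(got$n_matched, want$n)
})

test_that("build_network keeps edges passing both thresholds", {
  fx <- reference_fixture(simulation_config(seed = 5))
  one <- build_network(fx$spectra[1])
  expect_identical(nrow(one$nodes), 1L)
  expect_identical(nrow(one$edges), 0L)
  # two copies of one spectrum: a single cosine-1 edge
  s <- fx$spectra[[1]]
  s2 <- ms2_spectrum("copy", s$precursor_mz, s$polarity, s$rt, s$mz, s$intensity)
  net <- build_network(list(s, s2))
  expect_identical(nrow(net$edges), 1L)
  expect_equal(net$edges$cosine, 1, tolerance = 1e-9)
  expect_error(build_network(fx$spectra[1:68]), "mixed polarity")
})

test_that("the six IPC species cluster into one negative-mode component", {
  sp <- reference_species()
  fx <- reference_fixture(simulation_config(seed = 5),
                          species = sp[sp$class_id == "IPC", ])
  neg <- Filter(function(s) s$polarity == "negative", fx$spectra)
  expect_length(neg, 6L)
  net <- build_network(neg)
  g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                     vertices = net$nodes$feature_id)
  comp <- igraph::components(g)
  expect_equal(comp$no, 1)
})

test_that("topology: mutual top-K rule with lexicographic tie-break", {
  # star of 12 equal-cosine edges around node "c"
  others <- sprintf("n%02d", 1:12)
  edges <- data.frame(node_a = "c", node_b = others, cosine = 0.9,
                      n_matched = 5L, delta_mz = 0, stringsAsFactors = FALSE)
  net <- structure(list(
    nodes = data.frame(feature_id = c("c", others), precursor_mz = 0, rt = 0,
                       polarity = "positive", n_peaks = 0L),
    edges = edges, params = network_params()), class = "molecular_network")
  out <- enforce_topology(net, max_neighbors = 10, max_component = 100)
  expect_identical(nrow(out$edges), 10L)
  expect_setequal(out$edges$node_b, sprintf("n%02d", 1:10))
  # chain of 3 nodes, max_component = 2: the weakest edge goes
  net$edges <- data.frame(node_a = c("a", "b"), node_b = c("b", "x"),
                          cosine = c(0.9, 0.8), n_matched = 5L, delta_mz = 0)
  net$nodes <- data.frame(feature_id = c("a", "b", "x"), precursor_mz = 0,
                          rt = 0, polarity = "positive", n_peaks = 0L)
  out <- enforce_topology(net, max_neighbors = 10, max_component = 2)
  expect_identical(out$edges$cosine, 0.9)
})

test_that("topology bounds hold on random graphs", {
  set.seed(77)
  for (k in 1:10) {
    n <- 30L
    ids <- sprintf("v%02d", 1:n)
    m <- 120L
    pairs <- t(replicate(m, sort(sample.int(n, 2))))
    keyed <- !duplicated(paste(pairs[, 1], pairs[, 2]))
    pairs <- pairs[keyed, , drop = FALSE]
    edges <- data.frame(node_a = ids[pairs[, 1]], node_b = ids[pairs[, 2]],
                        cosine = round(runif(nrow(pairs), 0.7, 1), 3),
                        n_matched = 5L, delta_mz = 0, stringsAsFactors = FALSE)
    net <- structure(list(
      nodes = data.frame(feature_id = ids, precursor_mz = 0, rt = 0,
                         polarity = "positive", n_peaks = 0L),
      edges = edges, params = network_params()), class = "molecular_network")
    out <- enforce_topology(net, max_neighbors = 4, max_component = 10)
    deg <- table(c(out$edges$node_a, out$edges$node_b))
    expect_lte(max(c(deg, 0)), 4)
    if (nrow(out$edges)) {
      g <- igraph::graph_from_data_frame(out$edges[, 1:2], directed = FALSE,
                                         vertices = ids)
      expect_lte(max(igraph::components(g)$csize), 10)
    }
  }
})

test_that("library matching finds the right species and applies thresholds", {
  fx <- reference_fixture(simulation_config(seed = 5))
  truth <- attr(fx$features, "true_species")
  library_sp <- lapply(seq_along(fx$spectra), function(i) {
    s <- fx$spectra[[i]]
    s$name <- truth[i]
    s
  })
  # query: an LPC 16:0 spectrum simulated under a different seed
  q <- simulate_spectrum("LPC 16:0", "positive",
                         simulation_config(seed = 99, mz_jitter_sd = 0.001))
  hits <- match_library(q, library_sp)
  expect_gt(nrow(hits), 0L)
  expect_identical(hits$name[1], "LPC 16:0")
  expect_true(all(hits$cosine > 0.7 & hits$n_matched >= 6))
  # five shared peaks only: below the 6-peak library threshold
  s <- preprocess_spectrum(fx$spectra[[1]])
  five <- ms2_spectrum("q", s$precursor_mz, s$polarity, 1,
                       mz = s$mz[1:5], intensity = s$intensity[1:5])
  lib1 <- list({x <- fx$spectra[[1]]; x$name <- "ref"; x})
  expect_identical(nrow(match_library(five, lib1)), 0L)
  expect_identical(nrow(match_library(q, list())), 0L)
})

test_that("GraphML export round-trips node and edge attributes", {
  fx <- reference_fixture(simulation_config(seed = 5))
  neg <- Filter(function(s) s$polarity == "negative", fx$spectra)[1:4]
  net <- build_network(neg)
  ann <- annotate_spectra(neg)
  smry <- summarize_by_extract(ann, fx$features)
  p <- withr::local_tempfile(fileext = ".graphml")
  export_graph(net, p, annotations = ann, proportions = smry$nodes)
  g <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_true(all(c("precursor_mz", "rt", "class", "shorthand", "hexane") %in%
                    igraph::vertex_attr_names(g)))
  props <- igraph::vertex_attr(g, "hexane") +
    igraph::vertex_attr(g, "CHCl3") + igraph::vertex_attr(g, "MeOH")
  expect_equal(props, rep(1, 4), tolerance = 1e-9)
  if (igraph::gsize(g) > 0) {
    expect_true("cosine" %in% igraph::edge_attr_names(g))
  }
  # empty network exports a loadable empty graph
  empty <- structure(list(
    nodes = data.frame(feature_id = character(0), precursor_mz = numeric(0),
                       rt = numeric(0), polarity = character(0),
                       n_peaks = integer(0)),
    edges = data.frame(node_a = character(0), node_b = character(0),
                       cosine = numeric(0), n_matched = integer(0),
                       delta_mz = numeric(0)),
    params = network_params()), class = "molecular_network")
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_graph(empty, p2)
  expect_equal(igraph::gorder(igraph::read_graph(p2, format = "graphml")), 0)
})
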