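# Rule table audit, class detection, formula/chain inference, shorthand.

test_that("rule table covers every quoted diagnostic m/z within 5 ppm", {
  rules <- builtin_rules()
  manifest <- quoted_fragment_manifest()
  all_rule_formulas <- unique(unlist(lapply(rules, rule_formulas)))
  canon <- vapply(all_rule_formulas,
                  function(f) format_formula(parse_formula(f)), character(1))
  for (i in seq_len(nrow(manifest))) {
    th <- ion_mz(manifest$formula[i], manifest$charge[i])
    expect_lt(abs(ppm_error(manifest$printed[i], th)), 5,
              label = paste("ppm for", manifest$formula[i]))
  }
  # the fixed-formula diagnostic ions of the manifest appear in the rules
  # (precursor-dependent fragments such as carboxylates are chain-derived)
  fixed <- setdiff(manifest$formula, c("C18H35O2", "C21H42O6P", "C21H42O7P",
                                       "C3H8O5P", "C6H8O7P"))
  present <- fixed %in% canon
  expect_true(all(present),
              info = paste("missing:", paste(fixed[!present], collapse = ", ")))
})

test_that("key class rules carry their signature items", {
  rules <- builtin_rules()
  find_rule <- function(cls, pol) {
    Filter(function(r) r$class_id == cls && r$polarity == pol, rules)[[1]]
  }
  expect_true("C5H15NO4P" %in% rule_formulas(find_rule("GPC", "positive")))
  expect_true("C6H12O9P" %in% rule_formulas(find_rule("IPC", "negative")))
  # phosphoric acid loss, written in Hill order
  gpa <- find_rule("GPA", "positive")
  expect_true(format_formula(parse_formula("H3PO4")) %in% rule_formulas(gpa))
  # every class/polarity rule demands at least one required item
  for (r in rules) expect_gte(r$min_required, 1L)
})

test_that("class detection ranks the true class first on clean templates", {
  cfg <- simulation_config(seed = 7)
  cases <- list(
    c("LPI 18:0", "negative", "GPI"),
    c("LPI 18:0", "positive", "GPI"),
    c("LPG O-14:0", "negative", "GPG"),
    c("LPE 16:1", "positive", "GPE"),
    c("LPA 18:0", "negative", "GPA"),
    c("CPA 16:0", "negative", "cGPA"),
    c("LPS 18:0", "positive", "GPS"),
    c("LPC 16:0", "positive", "GPC"),
    c("IPC (d18:1/16:0)", "negative", "IPC"),
    c("FA 20:4;O3", "negative", "PG")
  )
  for (cs in cases) {
    s <- simulate_spectrum(cs[1], cs[2], cfg)
    cands <- detect_class(s)
    expect_gt(nrow(cands), 0L, label = paste("candidates for", cs[1]))
    expect_identical(cands$class_id[1], cs[3],
                     info = paste(cs[1], cs[2]))
  }
  # empty spectrum: no candidates
  empty <- ms2_spectrum("e", 500, "negative", 1, numeric(0), numeric(0))
  expect_identical(nrow(detect_class(empty)), 0L)
})

test_that("IPC outranks GPI on ceramide spectra and vice versa", {
  cfg <- simulation_config(seed = 7)
  ipc <- simulate_spectrum("IPC (d18:1/16:0)", "negative", cfg)
  cands <- detect_class(ipc)
  expect_identical(cands$class_id[1], "IPC")
  # the shared 259.0224/241.0119 ions alone must not make a GPI spectrum IPC
  gpi <- simulate_spectrum("LPI 18:0", "negative", cfg)
  cands <- detect_class(gpi)
  expect_false("IPC" %in% cands$class_id[1])
  a_ipc <- annotate_spectrum(ipc)
  a_gpi <- annotate_spectrum(gpi)
  expect_identical(a_ipc$class_id, "IPC")
  expect_identical(a_gpi$class_id, "GPI")
  # the IPC precursor formula carries nitrogen, the GPI one does not
  expect_true("N" %in% names(parse_formula(a_ipc$neutral_formula)))
  expect_false("N" %in% names(parse_formula(a_gpi$neutral_formula)))
})

test_that("precursor formula inference recovers published ion formulas", {
  # LPI 18:0 positive
  f <- infer_precursor_formula(601.3344, "positive", "GPI")
  expect_identical(f$ion_formula[1], "C27H54O12P")
  # LPG O-14:0: ether linkage required, no acyl solution in tolerance
  f <- infer_precursor_formula(443.2779, "positive", "GPG")
  expect_identical(f$ion_formula[1], "C20H44O8P")
  expect_identical(f$n_ester[1], 0L)
  # prostaglandin-type FA 20:4;O3
  f <- infer_precursor_formula(351.2178, "negative", "PG")
  expect_identical(f$ion_formula[1], "C20H31O5")
  expect_identical(f$neutral_formula[1], "C20H32O5")
  # all reported candidates sit inside the ppm tolerance
  expect_true(all(abs(f$ppm) <= 5))
  # nothing within tolerance of a nonsense mass
  expect_identical(nrow(infer_precursor_formula(123.4567, "negative", "GPI")),
                   0L)
})

test_that("chain inference pins chains from release fragments", {
  cfg <- simulation_config(seed = 7)
  # positive LPI 18:0: acyl chain via the glycerylphosphorylinositol loss
  s <- simulate_spectrum("LPI 18:0", "positive", cfg)
  ch <- infer_chain(s, "GPI", "C27H53O12P")
  expect_identical(ch$confidence, "species")
  expect_identical(ch$chains$carbons, 18L)
  expect_identical(ch$chains$db, 0L)
  expect_identical(ch$chains$linkage, "acyl")
  # LPS 18:0 positive: serine-loss peak near the published 421.2714
  s <- simulate_spectrum("LPS 18:0", "positive", cfg)
  serine_loss <- s$precursor_mz - monoisotopic_mass("C3H7NO3")
  expect_lt(abs(ppm_error(421.2714, serine_loss)), 5)
  expect_true(any(abs(s$mz - serine_loss) < 0.005))
  # precursor-only spectrum: arithmetic fallback, ambiguous -> class-only
  bare <- ms2_spectrum("b", 601.3348, "positive", 23, 601.3348, 100)
  ch <- infer_chain(bare, "GPI", "C27H53O12P")
  expect_identical(ch$confidence, "class")
  expect_identical(ch$chains$carbons, 18L)
})

test_that("oxidized two-chain species are split via carboxylate evidence", {
  cfg <- simulation_config(seed = 7)
  for (nm in c("PI 18:0/5:1;O2", "PI 18:0/6:1;O", "PI O-18:0/6:1;O2",
               "PI 18:0/9:2;O3")) {
    s <- simulate_spectrum(nm, "negative", cfg)
    a <- annotate_spectrum(s)
    expect_identical(a$shorthand, nm)
    expect_identical(a$confidence, "species")
  }
})

test_that("shorthand grammar matches the published naming", {
  expect_identical(shorthand_name("GPI", data.frame(
    carbons = 18L, db = 0L, oxy = 0L, linkage = "acyl")), "LPI 18:0")
  expect_identical(shorthand_name("GPG", data.frame(
    carbons = 14L, db = 0L, oxy = 0L, linkage = "ether")), "LPG O-14:0")
  expect_identical(shorthand_name("PG", data.frame(
    carbons = 20L, db = 4L, oxy = 3L, linkage = "sum")), "FA 20:4;O3")
  expect_identical(shorthand_name("cGPA", data.frame(
    carbons = 16L, db = 1L, oxy = 0L, linkage = "acyl")), "CPA 16:1")
  expect_identical(shorthand_name("IPC", rbind(
    data.frame(carbons = 18L, db = 1L, oxy = 0L, linkage = "sphingoid"),
    data.frame(carbons = 16L, db = 0L, oxy = 0L, linkage = "acyl"))),
    "IPC (d18:1/16:0)")
  # parse/format round trip across all reference names
  for (nm in reference_species()$name) {
    ps <- parse_shorthand(nm)
    expect_identical(shorthand_name(ps$class_id, ps$chains), nm)
  }
})

test_that("annotation returns nothing for noise and honors the tolerance", {
  set.seed(99)
  noise <- ms2_spectrum("n", 512.3456, "negative", 5,
                        mz = runif(20, 100, 500), intensity = runif(20, 1, 100))
  expect_null(annotate_spectrum(noise))
  # every produced annotation stays inside the precursor tolerance
  fx <- reference_fixture(simulation_config(seed = 7))
  ann <- annotate_spectra(fx$spectra)
  expect_true(all(abs(ann$precursor_ppm) <= annotation_params()$precursor_tol_ppm))
})

test_that("annotations survive seeded noise and jitter", {
  clean <- reference_fixture(simulation_config(seed = 42))
  noisy <- reference_fixture(simulation_config(
    seed = 42, n_noise_peaks = 10L, noise_rel_intensity_max = 0.05,
    mz_jitter_sd = 0.001))
  ann_c <- annotate_spectra(clean$spectra)
  ann_n <- annotate_spectra(noisy$spectra)
  key_c <- paste(ann_c$feature_id, ann_c$class_id, ann_c$sum_composition)
  key_n <- paste(ann_n$feature_id, ann_n$class_id, ann_n$sum_composition)
  unchanged <- sum(key_c %in% key_n)
  expect_gte(unchanged / length(clean$spectra), 0.95)
})
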