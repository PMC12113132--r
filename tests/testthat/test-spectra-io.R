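# Spectrum model, MGF and feature-table I/O.

make_mgf <- function(path, blocks) {
  writeLines(unlist(blocks), path)
  path
}

test_that("MGF reader parses blocks, polarity and retention time", {
  p <- withr::local_tempfile(fileext = ".mgf")
  make_mgf(p, list(
    c("BEGIN IONS", "FEATURE_ID=1", "PEPMASS=601.3344", "CHARGE=1+",
      "RTINSECONDS=1380", "267.2679 40.0", "335.0738 60.0", "END IONS", ""),
    c("BEGIN IONS", "FEATURE_ID=2", "PEPMASS=599.3202", "CHARGE=1-",
      "RTINMINUTES=23.0", "259.0224 100.0", "END IONS", "")
  ))
  sp <- read_mgf(p)
  expect_length(sp, 2L)
  expect_equal(sp[[1]]$precursor_mz, 601.3344)
  expect_identical(sp[[1]]$polarity, "positive")
  expect_equal(sp[[1]]$rt, 23)               # seconds converted to minutes
  expect_identical(sp[[2]]$polarity, "negative")  # CHARGE=1- convention
  expect_equal(sp[[2]]$rt, 23)
  expect_equal(sp[[1]]$mz, c(267.2679, 335.0738))  # sorted ascending
})

test_that("MGF blocks lacking PEPMASS fail with the block index", {
  p <- withr::local_tempfile(fileext = ".mgf")
  make_mgf(p, list(
    c("BEGIN IONS", "FEATURE_ID=1", "PEPMASS=400.1", "CHARGE=1+",
      "100.0 1.0", "END IONS"),
    c("BEGIN IONS", "FEATURE_ID=2", "CHARGE=1+", "100.0 1.0", "END IONS")))
  expect_error(read_mgf(p), "block 2.*PEPMASS")
})

test_that("empty peak lists are retained with a warning", {
  p <- withr::local_tempfile(fileext = ".mgf")
  make_mgf(p, list(c("BEGIN IONS", "FEATURE_ID=9", "PEPMASS=500.0",
                     "CHARGE=1-", "END IONS")))
  expect_warning(sp <- read_mgf(p), "empty peak list")
  expect_length(sp, 1L)
  expect_length(sp[[1]]$mz, 0L)
})

test_that("write_mgf / read_mgf round-trips spectra", {
  fx <- reference_fixture(simulation_config(seed = 3))
  p <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(fx$spectra, p)
  back <- read_mgf(p)
  expect_length(back, length(fx$spectra))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$feature_id, fx$spectra[[i]]$feature_id)
    expect_identical(back[[i]]$polarity, fx$spectra[[i]]$polarity)
    expect_equal(back[[i]]$precursor_mz, fx$spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$mz, fx$spectra[[i]]$mz, tolerance = 1e-4)
    expect_equal(back[[i]]$intensity, fx$spectra[[i]]$intensity,
                 tolerance = 1e-3)
  }
  # empty list gives a valid (empty) file
  p2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(), p2)
  expect_length(read_mgf(p2), 0L)
})

test_that("feature table reader parses the FBMN CSV dialect", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "row ID,row m/z,row retention time,hexane Peak area,CHCl3 Peak area,MeOH Peak area",
    "1,601.3344,23.0,700,200,100",
    "2,599.3202,23.0,70,20,10",
    "3,351.2178,19.0,15,70,15"), p)
  ft <- read_feature_table(p)
  expect_identical(nrow(ft), 3L)
  expect_identical(attr(ft, "samples"), c("hexane", "CHCl3", "MeOH"))
  expect_equal(ft$hexane, c(700, 70, 15))
})

test_that("feature table rejects duplicates, negatives and all-zero rows", {
  header <- "row ID,row m/z,row retention time,hexane Peak area,CHCl3 Peak area"
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(header, "1,400,10,5,5", "1,401,11,5,5"), p)
  expect_error(read_feature_table(p), "duplicate feature id")
  writeLines(c(header, "1,400,10,-5,5"), p)
  expect_error(read_feature_table(p), "negative")
  writeLines(c(header, "1,400,10,0,0"), p)
  expect_error(read_feature_table(p), "all-zero")
})

test_that("feature table write/read round-trips areas", {
  fx <- reference_fixture(simulation_config(seed = 3))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fx$features, p)
  back <- read_feature_table(p)
  expect_identical(back$feature_id, fx$features$feature_id)
  for (s in attr(back, "samples")) {
    expect_equal(back[[s]], fx$features[[s]], tolerance = 1e-6)
  }
})

test_that("link_features joins by id and reports the unmatched", {
  fx <- reference_fixture(simulation_config(seed = 3))
  linked <- link_features(fx$spectra, fx$features)
  expect_length(linked$spectra, length(fx$spectra))  # generator ids match 100%
  expect_length(linked$unmatched_spectra, 0L)
  expect_length(linked$unmatched_features, 0L)
  # disjoint ids: empty join plus warnings on both sides
  s2 <- fx$spectra[[1]]
  s2$feature_id <- "nope"
  expect_warning(expect_warning(
    l2 <- link_features(list(s2), fx$features[1:2, ]),
    "without feature record"), "without spectrum")
  expect_length(l2$spectra, 0L)
})

test_that("spectrum constructor sorts peaks and merges 1e-6 duplicates", {
  s <- ms2_spectrum("x", 500, "positive", 1,
                    mz = c(300, 100, 100 + 5e-7), intensity = c(1, 2, 3))
  expect_equal(s$mz, c(100, 300))
  expect_equal(s$intensity, c(5, 1))
  expect_error(ms2_spectrum("x", -1, "positive", 1, 100, 1), "precursor_mz")
  expect_error(ms2_spectrum("x", 500, "positive", 1, 100, -1), "non-negative")
})
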