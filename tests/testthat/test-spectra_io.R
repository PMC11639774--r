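test_that("MGF round trip preserves spectra to 6 decimals", {
  sp <- list(
    ms2_spectrum("a", 500.1234, 3.2, c(120.5, 80.1, 300.123456),
                 c(10, 20, 30)),
    ms2_spectrum("b", 773.192, 5.446, c(303.0496, 465.1027, 611.139))
  )
  tmp <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, tmp)
  back <- read_mgf(tmp)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$spectrum_id, sp[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_mz, sp[[i]]$precursor_mz, tolerance = 1e-6)
    expect_equal(back[[i]]$retention_time, sp[[i]]$retention_time,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$peaks$mz, sp[[i]]$peaks$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$peaks$intensity, sp[[i]]$peaks$intensity,
                 tolerance = 1e-6)
  }
  # peaks come back sorted ascending
  expect_true(all(diff(back[[1]]$peaks$mz) > 0))
})

test_that("MGF blocks lacking PEPMASS are skipped with a warning", {
  tmp <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=good", "PEPMASS=500.1", "RTINSECONDS=60",
               "100.1 5", "END IONS",
               "BEGIN IONS", "TITLE=bad", "100.2 5", "END IONS"), tmp)
  expect_warning(sp <- read_mgf(tmp), "PEPMASS")
  expect_length(sp, 1)
  expect_equal(sp[[1]]$spectrum_id, "good")
  expect_equal(sp[[1]]$retention_time, 1)  # seconds converted to minutes
  expect_equal(attr(sp, "parse_report")$n_skipped, 1L)
})

test_that("unparseable MGF peak lines raise an error naming the line", {
  tmp <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=500.1", "100.1 5", "oops nope",
               "END IONS"), tmp)
  expect_error(read_mgf(tmp), "line")
})

test_that("the shipped reference MGF reproduces the printed peak lists", {
  path <- system.file("extdata", "reference_spectra.mgf", package = "vitimet")
  sp <- read_mgf(path)
  expect_length(sp, 2)
  flav <- sp[[which(sapply(sp, `[[`, "spectrum_id") ==
                      "quercetin_coumaroyl_diglucoside")]]
  expect_equal(flav$precursor_mz, 773.1920)
  expect_equal(flav$peaks$mz, c(303.0496, 465.1027, 611.1390))
  expect_equal(flav$retention_time, 5.446, tolerance = 1e-6)
})

test_that("MSP round trip mirrors the MGF contract", {
  sp <- list(ms2_spectrum("x", 455.5, 2.0, c(100.5, 200.25), c(1, 2)))
  tmp <- withr::local_tempfile(fileext = ".msp")
  write_msp(sp, tmp)
  back <- read_msp(tmp)
  expect_equal(back[[1]]$precursor_mz, 455.5)
  expect_equal(back[[1]]$peaks$mz, c(100.5, 200.25))
  expect_equal(back[[1]]$retention_time, 2)
  writeLines(c("Name: broken", "Num Peaks: 1", "100.1 5"), tmp)
  expect_warning(b2 <- read_msp(tmp), "PrecursorMZ")
  expect_length(b2, 0)
})

test_that("quant CSV reader validates metadata and preserves order", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,s1,s2,s3,s4,s5,s6",
               "variety,v1,v1,v1,v2,v2,v2",
               "color,white,white,white,purple,purple,purple",
               "replicate,1,2,3,1,2,3",
               "F3,1,2,3,4,5,6",
               "F1,2,2,2,2,2,2",
               "F2,9,8,7,6,5,4",
               "F4,1,1,1,1,1,1",
               "F5,5,5,5,5,5,5"), tmp)
  qt <- read_quant_csv(tmp)
  expect_equal(dim(qt$values), c(5L, 6L))
  expect_equal(rownames(qt$values), c("F3", "F1", "F2", "F4", "F5"))
  expect_equal(qt$sample_meta$sample_id, paste0("s", 1:6))
  expect_equal(unname(qt$values["F3", "s4"]), 4)
})

test_that("quant CSV rejects unknown colors and duplicate features", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,s1,s2", "variety,v1,v2", "color,white,blue",
               "replicate,1,1", "F1,1,2"), tmp)
  expect_error(read_quant_csv(tmp), "blue")
  writeLines(c("feature_id,s1,s2", "variety,v1,v1", "color,white,white",
               "replicate,1,2", "F1,1,2", "F1,3,4"), tmp)
  expect_error(read_quant_csv(tmp), "duplicate feature")
})

test_that("blank cells are imputed at the half-minimum floor and counted", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature_id,s1,s2,s3", "variety,v1,v1,v1",
               "color,red,red,red", "replicate,1,2,3",
               "F1,4,,8"), tmp)
  qt <- read_quant_csv(tmp)
  expect_equal(unname(qt$values["F1", "s2"]), 2)  # half of min positive (4)
  rep <- attr(qt, "parse_report")
  expect_equal(rep$n_imputed, 1L)
  expect_equal(unname(rep$floor_values["F1"]), 2)
})

test_that("calibration series constructor enforces its preconditions", {
  expect_error(calibration_series("vc", c(1, 1), c(5, 6), 0.1, 1))
  expect_error(calibration_series("vc", 1, 5, 0.1, 1))
  cs <- calibration_series("vc", c(0, 5, 10), c(1, 50, 99), 0.1, 1)
  expect_s3_class(cs, "calibration_series")
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("analyte,concentration,response,sample_mass,extract_volume",
               "vc,0,1,0.1,1", "vc,10,99,0.1,1", "ve,0,2,0.1,1",
               "ve,4,42,0.1,1"), tmp)
  series <- read_calibration_csv(tmp)
  expect_setequal(names(series), c("vc", "ve"))
  expect_equal(series$vc$concentrations, c(0, 10))
})
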