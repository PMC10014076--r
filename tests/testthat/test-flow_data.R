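test_that("FCS fixtures round-trip through the reader", {
  ev <- matrix(c(10, 100, 20, 200, 30, 300), nrow = 3, byrow = TRUE)
  path <- write_fcs_fixture(ev, channels = c("BL1-A", "SSC-A"))
  tab <- read_fcs(path)
  expect_s3_class(tab, "event_table")
  expect_equal(nrow(tab$events), 3)
  expect_equal(tab$channels, c("BL1-A", "SSC-A"))
  expect_true("BL1-A" %in% tab$channels)
  expect_equal(unname(tab$events[, "BL1-A"]), c(10, 20, 30))
  expect_equal(tab$metadata[["$TOT"]], "3")
})

test_that("malformed and unsupported FCS files are rejected with context", {
  ev <- matrix(as.numeric(1:6), nrow = 3)
  # declared event count disagrees with the data segment length
  bad_tot <- write_fcs_fixture(ev, declared_tot = 5)
  expect_error(read_fcs(bad_tot), "format error.*byte offset")
  trunc <- write_fcs_fixture(ev, truncate_data = 2L)
  expect_error(read_fcs(trunc), "format error")
  old <- write_fcs_fixture(ev, version = "FCS2.0")
  expect_error(read_fcs(old), "unsupported FCS version")
})

test_that("log-amplified FCS parameters are converted to linear scale", {
  # stored value x on a 4-decade log amplifier over R=1024 channels means
  # linear FI = 10^(4 * x / 1024)
  ev <- matrix(c(0, 256, 512, 1024), ncol = 1)
  path <- write_fcs_fixture(ev, channels = "FL1",
                            extra_keywords = list("$P1E" = "4,0",
                                                  "$P1R" = "1024"))
  tab <- read_fcs(path)
  expect_equal(unname(tab$events[, 1]), 10^(4 * c(0, 256, 512, 1024) / 1024),
               tolerance = 1e-6)
})

test_that("CSV event reading enforces schema and numeric values", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("GFP,other", "10,a", "20,b", "30,c"), path)
  tab <- read_events_csv(path, "GFP")
  expect_equal(nrow(tab$events), 3)
  expect_equal(unname(tab$events[, "GFP"]), c(10, 20, 30))
  expect_error(read_events_csv(path, c("GFP", "FSC")), "schema error.*FSC")
  writeLines(c("GFP", "10", "NA", "30"), path)
  expect_error(read_events_csv(path, "GFP"), "parse error.*row 2")
})

test_that("event CSV round-trips a synthetic table within precision", {
  set.seed(4)
  ev <- matrix(round(rlnorm(60, 5, 1), 6), ncol = 2,
               dimnames = list(NULL, c("GFP", "FSC")))
  path <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(ev), path, row.names = FALSE)
  tab <- read_events_csv(path, c("GFP", "FSC"))
  expect_equal(unname(tab$events), unname(ev), tolerance = 1e-12)
})

test_that("intensity transforms follow their definitions", {
  expect_equal(transform_intensity(c(10, 100, 1000), "log10_floor"),
               c(1, 2, 3))
  # floor rule: values <= 0 replaced by half the smallest positive value
  expect_equal(transform_intensity(c(0, 10), "log10_floor"),
               c(log10(5), 1))
  expect_equal(transform_intensity(0, "arcsinh", cofactor = 150), 0)
  v <- c(-3, 0, 2.5, 1e4)
  expect_identical(transform_intensity(v, "identity"), v)
  expect_equal(transform_intensity(v, "arcsinh", cofactor = 150),
               asinh(v / 150))
  expect_error(transform_intensity(c(-1, 0), "log10_floor"),
               "degenerate input")
  expect_error(transform_intensity(c(1, 2), "arcsinh"), "cofactor")
})

test_that("assemble_dataset groups by condition and preserves cell counts", {
  sheet <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    receptor = rep(c("dectin2", "mincle"), each = 3),
    ligand = "furfurman", dose = rep(c(0, 1, 10), 2), dose_unit = "ug/ml",
    replicate = 1L, stimulation_hours = 16, output_channel = "GFP")
  tables <- lapply(c(30, 40, 50, 60, 70, 80), function(n) {
    event_table("x", "GFP", matrix(rlnorm(n, 5, 1), ncol = 1))
  })
  names(tables) <- sheet$sample_id
  out <- assemble_dataset(sheet, tables)
  expect_length(out, 2)
  ds <- out[["dectin2/furfurman/rep1"]]
  expect_equal(ds$doses, c(0, 1, 10))
  expect_equal(cells_per_dose(ds), c(30, 40, 50))
  expect_equal(ds$transform_tag, "log10_floor")
  expect_equal(cells_per_dose(out[["mincle/furfurman/rep1"]]), c(60, 70, 80))

  expect_error(assemble_dataset(sheet, tables[-1]), "linkage error.*s1")
  dup <- rbind(sheet, sheet[1, ])
  expect_error(assemble_dataset(dup, tables), "duplication error")
})

test_that("population summaries are geometric with multiplicative robust SD", {
  s <- summarize_population(c(10, 1000))
  expect_equal(s$geometric_mean, 100)
  s <- summarize_population(c(7, 7, 7))
  expect_equal(s$geometric_mean, 7)
  expect_equal(s$robust_sd, 1)
  v <- c(1, 2, 4, 8, 16)
  s <- summarize_population(v)
  expect_equal(s$geometric_mean, 4)
  expect_equal(s$robust_sd, exp(1.4826 * median(abs(log(v) - median(log(v))))))
  expect_error(summarize_population(c(1, 0)), "domain error")
})

test_that("bead calibration interpolates on the log-log line monotonically", {
  cal <- bead_calibration(data.frame(measured_fi = c(100, 1000),
                                     molecules = c(1000, 10000)))
  expect_equal(calibrate_fi_to_molecules(cal, 100), 1000, tolerance = 1e-9)
  expect_equal(calibrate_fi_to_molecules(cal, 316.23), 3162.3,
               tolerance = 1e-4)
  x <- sort(rlnorm(50, 5, 2))
  y <- calibrate_fi_to_molecules(cal, x)
  expect_true(all(diff(y) > 0))
  expect_error(bead_calibration(data.frame(measured_fi = 1, molecules = 10)),
               "fit error")
  expect_error(calibrate_fi_to_molecules(cal, c(10, -1)), "domain error")
})
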