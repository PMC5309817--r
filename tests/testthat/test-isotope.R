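test_that("delta/ratio/atom-percent algebra is mutually inverse", {
  refs <- reference_ratios()
  expect_equal(delta_from_ratio(refs$C, refs$C), 0)
  expect_equal(ratio_from_delta(1000, refs$C), 2 * refs$C)
  expect_equal(ratio_from_delta(delta_from_ratio(0.0123, refs$C), refs$C),
               0.0123, tolerance = 1e-15)
  # across the full enrichment range
  for (d in c(-900, -27, 0, 50, 1000, 10000)) {
    expect_equal(delta_from_ratio(ratio_from_delta(d, refs$N), refs$N), d,
                 tolerance = 1e-12)
    expect_equal(atom_percent_to_delta(delta_to_atom_percent(d, refs$C),
                                       refs$C), d, tolerance = 1e-9)
  }
  expect_error(delta_from_ratio(-0.01, refs$C), "> 0")
  expect_error(ratio_from_delta(-1000, refs$C), "-1000")
})

test_that("atom percent hits the analytic values at natural abundance", {
  refs <- reference_ratios()
  # oracle: 100 * R / (1 + R) at delta = 0
  expect_equal(delta_to_atom_percent(0, refs$C),
               100 * refs$C / (1 + refs$C))
  expect_equal(delta_to_atom_percent(0, refs$C), 1.10566, tolerance = 1e-5)
  expect_equal(delta_to_atom_percent(0, refs$N), 0.36630, tolerance = 1e-5)
  expect_equal(atom_percent(3, 3), 50)
  expect_error(atom_percent(1, 0), "light")
})

test_that("delta calibration is the exact two-point line at two standards", {
  std <- isotope_standards()
  cert <- std$d13C[std$name %in% c("USGS40", "USGS41")]
  cal <- calibrate_delta(c(-30, 40), cert, names = c("USGS40", "USGS41"))
  expect_equal(cal$slope, (37.63 + 26.39) / 70)
  expect_equal(cal$intercept, -26.39 + (37.63 + 26.39) / 70 * 30)
  expect_equal(cal$slope, 0.91457, tolerance = 1e-5)
  expect_equal(cal$intercept, 1.0471, tolerance = 1e-4)
  # each standard's own measurement corrects to its certified value
  expect_equal(predict(cal, c(-30, 40)), cert)
  # identity calibration
  id <- calibrate_delta(cert, cert)
  expect_equal(id$slope, 1)
  expect_equal(id$intercept, 0, tolerance = 1e-12)
  expect_error(calibrate_delta(-30, -26.39), ">= 2")
  expect_error(calibrate_delta(c(-30, -30), cert), "distinct")
})

test_that("overdetermined calibration equals the least-squares oracle", {
  set.seed(9)
  measured <- c(-31, -10.2, 36.9)
  certified <- c(-26.39, -10.45, 37.63) + rnorm(3, 0, 0.2)
  cal <- calibrate_delta(measured, certified)
  # normal-equations oracle
  mx <- mean(measured); my <- mean(certified)
  slope <- sum((measured - mx) * (certified - my)) / sum((measured - mx)^2)
  expect_equal(cal$slope, slope, tolerance = 1e-12)
  expect_equal(cal$intercept, my - slope * mx, tolerance = 1e-12)
  expect_equal(cal$residuals,
               certified - (slope * measured + my - slope * mx),
               tolerance = 1e-12)
})

test_that("excess is labelled minus control, flagged when below control", {
  expect_equal(as.numeric(excess_atom_percent(1.20, 1.08)), 0.12)
  expect_equal(as.numeric(excess_atom_percent(1.08, 1.08)), 0)
  e <- excess_atom_percent(1.05, 1.08)
  expect_equal(as.numeric(e), -0.03)
  expect_true(attr(e, "below_control"))
  expect_error(excess_atom_percent(150, 1), "\\[0, 100\\]")
})

test_that("element standard curve converts signal to micrograms", {
  # 100 ug sulfanilamide carries 41.84 ug C
  sulf <- element_standards()[1, ]
  curve <- element_curve(area = c(0, 10), mass_ug = c(0, 100),
                         pct = sulf$pct_C)
  expect_equal(curve$points$element_ug, c(0, 41.84))
  expect_equal(element_content(curve, 5), 41.84 / 2)
  expect_equal(element_content(curve, 0), 0, tolerance = 1e-12)
  expect_error(element_curve(5, 100, 41.84), "distinct")
})

test_that("biomarker map carries the standard assignments exactly", {
  map <- biomarker_map()
  expect_equal(sum(map$pool == "bacteria"), 11)
  expect_equal(map$pool[map$fatty_acid == "10Me16:0"], "actinomycetes")
  expect_equal(map$assay[map$fatty_acid == "18:2w6,9"], "PLFA")
  expect_equal(map[map$pool == "AMF", "assay"], "NLFA")
  over <- biomarker_map(overrides = data.frame(
    fatty_acid = "18:1w9", pool = "fungi", assay = "PLFA"))
  expect_true("18:1w9" %in% over$fatty_acid)
  expect_error(biomarker_map(overrides = data.frame(
    fatty_acid = c("x", "x"), pool = c("fungi", "bacteria"),
    assay = "PLFA")), "exactly one pool")
})

test_that("pool aggregation sums by marker and normalizes shares", {
  fa <- data.frame(
    fatty_acid = c("i15:0", "a15:0", "18:2w6,9", "16:1w5", "19:0"),
    assay = c("PLFA", "PLFA", "PLFA", "NLFA", "PLFA"),
    concentration = c(2, 3, 5, 4, 9),
    excess_13C = c(1, 1, 6, 2, 99)
  )
  expect_warning(out <- aggregate_pools(fa), "19:0")
  pools <- setNames(out$pools$concentration, out$pools$pool)
  expect_equal(pools[["bacteria"]], 5)
  expect_equal(pools[["fungi"]], 5)
  expect_equal(pools[["AMF"]], 4)  # NLFA marker never joins the PLFA sums
  expect_equal(sum(out$shares$pct_of_total_excess), 100)
  expect_error(aggregate_pools(fa[5, ]), "no fatty acid")
})

test_that("F:B ratios distinguish per-sample ratios from pooled sums", {
  expect_equal(fb_ratio(5, 5), 1)
  expect_equal(fb_ratio(0, 5), 0)
  s <- fb_ratio(c(1, 4), c(2, 2), summarize = TRUE)
  expect_equal(s$ratios, c(0.5, 2))
  expect_equal(s$mean, 1.25)          # mean of per-sample ratios
  expect_equal(sum(c(1, 4)) / sum(c(2, 2)), 1.25)
  # a case where mean-of-ratios and ratio-of-sums genuinely differ
  expect_equal(mean(fb_ratio(c(2, 8), c(4, 2))), 2.25)
  expect_equal(sum(c(2, 8)) / sum(c(4, 2)), 10 / 6)
  expect_error(fb_ratio(1, 0), "> 0")
})

test_that("channel partition conserves fractions and floors negatives", {
  b <- channel_partition(c(bacteria = 1, fungi = 2, AMF = 1),
                         root_excess = 8)
  expect_equal(setNames(b$fraction, b$pool),
               c(bacteria = 0.25, fungi = 0.5, AMF = 0.25))
  expect_equal(sum(b$fraction), 1, tolerance = 1e-9)
  expect_equal(setNames(b$root_scaled, b$pool),
               c(bacteria = 1 / 8, fungi = 2 / 8, AMF = 1 / 8))
  # fungi-only label
  b2 <- channel_partition(c(bacteria = 0, fungi = 3, AMF = 0), 1)
  expect_equal(b2$fraction[b2$pool == "fungi"], 1)
  # scale invariance
  b3 <- channel_partition(c(bacteria = 17, fungi = 34, AMF = 17), 8)
  expect_equal(b3$fraction, b$fraction)
  # negative excess floored and flagged, raw value preserved
  b4 <- channel_partition(c(bacteria = -0.05, fungi = 2), 4)
  expect_true(b4$floored[b4$pool == "bacteria"])
  expect_equal(b4$excess[b4$pool == "bacteria"], -0.05)
  expect_equal(b4$fraction, c(0, 1))
  expect_error(channel_partition(c(a = -1, b = 0), 1), "no label")
  expect_error(channel_partition(c(a = 1), 0), "root_excess")
})

test_that("a constructed three-quarters fungal channel is recovered", {
  # pools built so fungi hold 0.75 of the summed microbial excess,
  # the late-succession pattern scale
  b <- channel_partition(c(bacteria = 0.20, fungi = 0.75, AMF = 0.05),
                         root_excess = 2)
  expect_equal(b$fraction[b$pool == "fungi"], 0.75)
})

test_that("isotope reader validates kinds, ranges and degenerate input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(compartment = "roots", element = "C", time_point = "1d",
                   treatment = "labelled", value = 1.2,
                   value_kind = "atom_percent")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_isotope(path)
  expect_equal(nrow(out), 1)

  bad <- df; bad$value <- 150
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_isotope(path), "atom_percent outside")

  bad <- df; bad$element <- "P"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_isotope(path), "unknown element")

  write.table(df[0, ], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(out <- read_isotope(path), "empty")
  expect_equal(nrow(out), 0)
})

test_that("summarize_excess joins labelled and control means", {
  meas <- rbind(
    data.frame(compartment = "roots", element = "C", time_point = "1d",
               treatment = "labelled", value = c(3.0, 3.2),
               value_kind = "atom_percent"),
    data.frame(compartment = "roots", element = "C", time_point = "1d",
               treatment = "control", value = c(1.05, 1.15),
               value_kind = "atom_percent")
  )
  out <- summarize_excess(meas)
  expect_equal(out$excess, 3.1 - 1.1)
  expect_equal(out$n_labelled, 2L)
  # deltas convert through the reference before subtraction
  refs <- reference_ratios()
  meas$value_kind <- "delta_permil"
  meas$value <- atom_percent_to_delta(meas$value, refs$C)
  out2 <- summarize_excess(meas)
  expect_equal(out2$excess, out$excess, tolerance = 1e-12)
  expect_error(summarize_excess(meas[1:2, ]), "lacks")
})
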