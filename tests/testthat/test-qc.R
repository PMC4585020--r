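test_that("plate sample names parse and format round-trip", {
  p <- parse_sample_name(c("001_5186_01", "310_5186_03"))
  expect_equal(p$well, c(1L, 310L))
  expect_equal(p$sample_id, c(5186L, 5186L))
  expect_equal(p$replicate, c(1L, 3L))
  expect_equal(format_sample_name(p$well, p$sample_id, p$replicate),
               c("001_5186_01", "310_5186_03"))
  expect_error(parse_sample_name("385_1_01"), "out of range")
  expect_error(parse_sample_name("001_5186"), "three")
  expect_error(parse_sample_name("001_abc_01"), "non-numeric")
  expect_error(parse_sample_name("001_1_04"), "replicate")
})

test_that("export grids parse with warning row, NA padding and dropped columns", {
  lines <- worked_example_grid()
  grid <- parse_export_grid(lines, "lep")
  uw <- attr(grid, "unit_warnings")
  expect_equal(uw$warning[uw$unit == "CpG_1"], "L_mass")
  expect_equal(uw$warning[uw$unit == "CpG_3"], "SN3")
  # the all-NA column (unmeasurable unit) is dropped but logged
  expect_equal(attr(grid, "dropped_units"), "CpG_1")
  expect_setequal(unique(grid$unit), c("CpG_2", "CpG_3", "CpG_4"))
  # controls keep their literal labels
  expect_true(all(c("gDNA", "water") %in% grid$sample_id))
  expect_true(all(is.na(grid$value[grid$sample_id == "gDNA"])))
})

test_that("grid parse errors name the offending cell", {
  expect_error(parse_export_grid(c("Sample\tCpG_1")),
               "headerless|no sample rows")
  expect_error(parse_export_grid(character(0)), "Empty")
  expect_error(parse_export_grid(
    c("Sample\tCpG_1", "001_1_01\t0.5", "001_1_01\t0.6")), "Duplicate")
  expect_error(parse_export_grid(
    c("Sample\tCpG_1", "001_1_01\t1.5")), "outside")
  expect_error(parse_export_grid(
    c("Sample\tCpG_1", "001_1_01\tfoo")), "Non-numeric")
})

test_that("replicate collapsing applies the two cell-level rules", {
  grid <- tibble::tibble(
    sample_id = rep(c("a", "b", "c"), each = 3),
    unit = "CpG_2",
    value = c(0.70, 0.72, 0.71,   # sd 0.01 -> mean 0.71
              0.2, 0.5, 0.8,      # sd 0.30 -> missing
              0.5, NA, NA))       # one replicate -> missing
  out <- collapse_replicates(grid)
  expect_equal(out$value[out$sample_id == "a"], 0.71)
  expect_equal(out$rep_sd[out$sample_id == "a"], 0.01, tolerance = 1e-9)
  expect_true(is.na(out$value[out$sample_id == "b"]))
  expect_equal(out$reason[out$sample_id == "b"], "replicate_sd")
  expect_true(is.na(out$value[out$sample_id == "c"]))
  expect_equal(out$reason[out$sample_id == "c"], "too_few_replicates")
})

test_that("two good replicates are enough; the SD denominator is n-1", {
  grid <- tibble::tibble(sample_id = "a", unit = "u",
                         value = c(0.4, 0.5, NA))
  out <- collapse_replicates(grid)
  expect_equal(out$value, 0.45)
  expect_equal(out$rep_sd, sd(c(0.4, 0.5)))
})

test_that("the worked-example SDs retain 3 of 10 samples and drop the unit", {
  grid <- parse_export_grid(worked_example_grid(), "lep")
  coll <- collapse_replicates(grid)
  cpg3 <- coll[coll$unit == "CpG_3" &
                 !coll$sample_id %in% c("gDNA", "water"), ]
  expect_equal(sum(!is.na(cpg3$value)), 3)
  qc <- filter_units(coll)
  expect_false("CpG_3" %in% unique(qc$matrix$unit))
  log3 <- qc$exclusions[qc$exclusions$id == "CpG_3", ]
  expect_equal(log3$rule, "success_rate")
  expect_match(log3$detail, "3/10")
  expect_setequal(unique(qc$matrix$unit), c("CpG_2", "CpG_4"))
})

test_that("overlap-warned units are removed regardless of success rate", {
  coll <- tibble::tibble(
    sample_id = rep(c("1", "2"), each = 2),
    unit = rep(c("u1", "u2"), 2),
    value = c(0.5, 0.6, 0.5, 0.6))
  uw <- tibble::tibble(unit = c("u1", "u2"),
                       warning = c("OL_CpG_9", NA))
  qc <- filter_units(coll, unit_warnings = uw)
  expect_equal(unique(qc$matrix$unit), "u2")
  expect_equal(qc$exclusions$rule[qc$exclusions$id == "u1"],
               "mass_overlap")
  # and kept when remove_overlaps is off
  qc2 <- filter_units(coll, unit_warnings = uw, remove_overlaps = FALSE)
  expect_setequal(unique(qc2$matrix$unit), c("u1", "u2"))
})

test_that("SNP units are removed and controls leave the denominator", {
  coll <- tibble::tibble(
    sample_id = rep(c("1", "2", "gDNA"), each = 2),
    unit = rep(c("u1", "u2"), 3),
    value = c(0.5, 0.6, 0.5, 0.6, NA, NA))
  qc <- filter_units(coll, snp_units = "u2")
  expect_equal(unique(qc$matrix$unit), "u1")
  expect_false("gDNA" %in% qc$matrix$sample_id)
  # controls do not drag the success rate down
  expect_equal(qc$success_rates$success_rate[
    qc$success_rates$unit == "u1"], 1.0)
})

test_that("filtering is idempotent and the log accounts for every removal", {
  grid <- parse_export_grid(worked_example_grid(), "lep")
  coll <- collapse_replicates(grid)
  qc1 <- filter_units(coll)
  qc2 <- filter_units(qc1$matrix, exclude = character(0))
  expect_equal(qc2$matrix, qc1$matrix)
  units_in <- unique(coll$unit[!coll$sample_id %in% c("gDNA", "water")])
  removed <- qc1$exclusions$id[qc1$exclusions$scope == "unit"]
  expect_setequal(c(unique(qc1$matrix$unit), removed), units_in)
})

test_that("lowering the SD cutoff never adds retained cells", {
  grid <- parse_export_grid(worked_example_grid(), "lep")
  cutoffs <- c(0.3, 0.15, 0.1, 0.05, 0.01)
  retained <- vapply(cutoffs, function(ct)
    sum(!is.na(collapse_replicates(grid, sd_cutoff = ct)$value)),
    numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("lowering the success cutoff never loses units", {
  grid <- parse_export_grid(worked_example_grid(), "lep")
  coll <- collapse_replicates(grid)
  cutoffs <- c(1.0, 0.8, 0.5, 0.2, 0)
  n_units <- vapply(cutoffs, function(ct)
    length(unique(filter_units(coll, success_cutoff = ct)$matrix$unit)),
    numeric(1))
  expect_true(all(diff(n_units) >= 0))
})

test_that("multimodality flagging needs 20 values and a real split", {
  set.seed(9)
  uni <- pmin(1, pmax(0, rnorm(100, 0.7, 0.03)))
  expect_false(flag_multimodal(uni)$multimodal)
  bi <- c(pmin(1, pmax(0, rnorm(50, 0.2, 0.03))),
          pmin(1, pmax(0, rnorm(50, 0.8, 0.03))))
  fb <- flag_multimodal(bi)
  expect_true(fb$multimodal)
  expect_gt(fb$delta_mean, 0.2)
  small <- flag_multimodal(runif(10))
  expect_false(small$assessable)
  expect_false(small$multimodal)
  const <- flag_multimodal(rep(0.5, 30))
  expect_true(const$assessable)
  expect_false(const$multimodal)
  expect_match(const$note, "degenerate")
})

test_that("a close or lopsided mixture is not called multimodal", {
  set.seed(10)
  close_means <- c(rnorm(50, 0.45, 0.03), rnorm(50, 0.55, 0.03))
  expect_false(flag_multimodal(close_means)$multimodal)
  lopsided <- c(rnorm(95, 0.3, 0.03), rnorm(5, 0.9, 0.03))
  expect_false(flag_multimodal(lopsided)$multimodal)
})

test_that("conversion scores follow the intensity ratio", {
  expect_equal(conversion_score(converted = 99, unconverted = 1), 1.0)
  expect_equal(conversion_score(converted = 0, unconverted = 5), 100)
  expect_true(is.na(conversion_score(converted = 0, unconverted = 0)))
  expect_error(conversion_score(converted = -1, unconverted = 1),
               "non-negative")
  tab <- tibble::tibble(well = c(1, 1, 2, 3),
                        converted = c(99, 97, 50, 0),
                        unconverted = c(1, 3, 50, 0))
  sc <- conversion_score(tab)
  expect_equal(sc$score[sc$well == 1], 2)
  expect_equal(sc$score[sc$well == 2], 50)
  expect_true(is.na(sc$score[sc$well == 3]))
})

test_that("plate design fills distinct wells deterministically", {
  expect_equal(plate_capacity(), 126)
  lay1 <- design_plate(1:10, seed = 42)
  lay2 <- design_plate(1:10, seed = 42)
  expect_identical(lay1, lay2)
  lay3 <- design_plate(1:10, seed = 43)
  expect_false(identical(lay1, lay3))
  expect_equal(nrow(lay1), (10 + 2) * 3)
  expect_false(any(duplicated(lay1$well)))
  per <- table(lay1$sample_id)
  expect_true(all(per == 3))
  expect_true(all(c("water", "gDNA") %in% names(per)))
  expect_true(all(grepl("^[0-9]{3}_.+_[0-9]{2}$", lay1$label)))
  one <- design_plate("7", seed = 1)
  expect_equal(sum(!one$is_control), 3)
  expect_error(design_plate(1:127, seed = 1), "capacity of 126")
})
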