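test_that("leptin design evaluation reproduces the published unit table", {
  rep <- amplicon_report(lep_amplicon())
  u <- rep$units
  expect_equal(nrow(u), 5)
  expect_equal(u$desc, paste0("CpG_", 1:5))
  expect_true("L_MASS" %in% u$warnings[[1]])
  expect_equal(u$base_mass[2:5],
               c(2260.426, 2509.587, 4524.87, 2878.821),
               tolerance = 0.05)
  expect_equal(rep$measurable_count, 4)
  # no duplicate, overlap or near warnings among the in-window units
  expect_false(any(unlist(u$warnings[2:5]) %in%
                     c("DUP", "OVERLAP", "NEAR")))
  expect_true(all(is.na(u$nearest_da)))
  tab <- report_table(rep)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$Name, paste0("CpG_Unit_", 2:5))
  expect_true(all(is.na(tab$`< 15.9 Da`)))
})

test_that("mass-window warnings follow the window rule", {
  m <- mass_model()
  # forward T runs template transcript A runs, so a CpG flanked by long T
  # stretches sits in one huge U-free fragment
  amp <- paste0("A", strrep("T", 25), "CG", strrep("T", 10), "A")
  u <- enumerate_cpg_units(amp, m)
  expect_true(any(u$base_mass > 7000))
  expect_true("H_MASS" %in% unlist(u$warnings))
  expect_false(all(u$measurable))
})

test_that("identical-composition units are flagged as duplicates", {
  u <- enumerate_cpg_units("AACGTAACGT")
  fr <- fragment_amplicon("AACGTAACGT")
  u <- detect_collisions(u, fr)
  expect_equal(nrow(u), 2)
  expect_true(all(vapply(u$warnings, function(w) "DUP" %in% w,
                         logical(1))))
  expect_true(all(vapply(u$warnings, function(w) "OVERLAP" %in% w,
                         logical(1))))
  expect_false(any(u$measurable))
})

test_that("a silent fragment near a methylated state triggers SILENT_OVERLAP", {
  unit <- tibble::tibble(
    name = "CpG_Unit_1", desc = "CpG_1", fragment = 1L,
    fwd_start = 1L, fwd_end = 10L, n_cpg = 1L, cpg_sites = list(1L),
    base_mass = 2000, mass_states = list(c(2000, 2016)),
    warnings = list(character(0)), snp_overlap = FALSE,
    nearest_da = NA_real_, measurable = TRUE)
  silent <- tibble::tibble(fragment = 2L, n_cpg = 0L, base_mass = 2016.0)
  out <- detect_collisions(unit, silent)
  expect_true("SILENT_OVERLAP" %in% out$warnings[[1]])
  # silent overlap alone does not kill measurability
  expect_true(out$measurable[1])
})

test_that("near neighbours record their distance; NEAR excludes OVERLAP", {
  mk <- function(mass, id) tibble::tibble(
    name = paste0("CpG_Unit_", id), desc = paste0("CpG_", id),
    fragment = id, fwd_start = 1L, fwd_end = 10L, n_cpg = 1L,
    cpg_sites = list(id), base_mass = mass,
    mass_states = list(c(mass, mass + 16)),
    warnings = list(character(0)), snp_overlap = FALSE,
    nearest_da = NA_real_, measurable = TRUE)
  units <- dplyr::bind_rows(mk(2000, 1L), mk(2024, 2L))
  out <- detect_collisions(units, tibble::tibble(fragment = integer(),
                                                 n_cpg = integer(),
                                                 base_mass = numeric()))
  # closest pair: 2016 vs 2024 -> 8 Da
  expect_true(all(vapply(out$warnings, function(w) "NEAR" %in% w,
                         logical(1))))
  expect_false(any(vapply(out$warnings, function(w) "OVERLAP" %in% w,
                          logical(1))))
  expect_equal(out$nearest_da, c(8, 8))
  expect_true(all(out$measurable))
})

test_that("conversion controls satisfy all four predicates", {
  rep <- amplicon_report(lep_amplicon())
  ctrl <- rep$controls
  expect_gt(nrow(ctrl), 0)
  expect_true(all(ctrl$n_cpg == 0))
  expect_true(all(ctrl$converted_c >= 1))
  expect_true(all(ctrl$base_mass >= 1500 & ctrl$base_mass <= 7000))
  # unconverted satellites keep clear of every other fragment mass
  all_states <- unlist(lapply(seq_len(nrow(rep$fragments)), function(i)
    rep$fragments$base_mass[i] + 16 * 0:rep$fragments$n_cpg[i]))
  for (i in seq_len(nrow(ctrl))) {
    sat <- ctrl$unconverted_masses[[i]]
    others <- all_states[-match(ctrl$base_mass[i], all_states)]
    expect_true(all(vapply(sat, function(m)
      all(abs(others - m) > 1), logical(1))))
  }
})

test_that("fragments without converted cytosines or with CpGs are not controls", {
  fr <- fragment_amplicon(lep_amplicon())
  ctrl <- find_conversion_controls(fr)
  expect_false(any(ctrl$n_cpg > 0))
  expect_false(any(ctrl$converted_c == 0))
})

test_that("every CpG site appears in exactly one unit", {
  set.seed(202)
  for (i in 1:20) {
    s <- random_dna(80)
    u <- enumerate_cpg_units(s)
    expect_equal(sort(unlist(u$cpg_sites)),
                 seq_len(count_cpg_sites(s)))
  }
})

test_that("widening the mass window never loses measurable units", {
  set.seed(303)
  for (i in 1:15) {
    s <- random_dna(120)
    narrow <- amplicon_report(s, mass_model(min_mass = 2000,
                                            max_mass = 5000))
    wide <- amplicon_report(s, mass_model(min_mass = 1500,
                                          max_mass = 7000))
    expect_gte(wide$measurable_count, narrow$measurable_count)
  }
})

test_that("a CpG-free amplicon gives an empty unit table", {
  rep <- amplicon_report("TTATTATTAAGGGATT")
  expect_equal(nrow(rep$units), 0)
  expect_match(rep$verdict, "0 of 0")
  expect_equal(nrow(report_table(rep)), 0)
})

test_that("SNP-masked fragments carry snp_overlap", {
  amp <- parse_annotated_sequence("TTA<C>GTTTTAACGTT")
  u <- enumerate_cpg_units(amp)
  expect_equal(u$snp_overlap, c(TRUE, FALSE))
})

test_that("the T report file round-trips through the grid dialect", {
  rep <- amplicon_report(lep_amplicon())
  path <- tempfile(fileext = ".txt")
  write_t_report(rep, path, provenance = "# test")
  lines <- readLines(path)
  expect_equal(lines[1], "# test")
  expect_equal(strsplit(lines[2], "\t")[[1]],
               c("Name", "Base mass", "Desc", "< 15.9 Da"))
  expect_equal(length(lines), 2 + 4)
  body <- read.delim(path, comment.char = "#", check.names = FALSE)
  expect_equal(body$`Base mass`,
               c(2260.426, 2509.587, 4524.87, 2878.821), tolerance = 0.05)
})

test_that("tidy and glance summarise a report", {
  rep <- amplicon_report(lep_amplicon())
  td <- tidy(rep)
  expect_equal(nrow(td), 5)
  expect_match(td$warnings[1], "L_MASS")
  gl <- glance(rep)
  expect_equal(gl$n_cpg_sites, 5)
  expect_equal(gl$n_measurable, 4)
})
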