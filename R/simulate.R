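#' Methylation ratio from peak areas
#'
#' The methylation fraction of a CpG unit is the surface area of the peak
#' of the methylated fragment divided by the total area of the methylated
#' and unmethylated peaks.
#'
#' @param area_methylated,area_unmethylated Non-negative peak areas.
#' @return Fraction in \[0,1\]; NA where both areas are zero.
#' @examples
#' methylation_ratio(30, 70)
#' @export
methylation_ratio <- function(area_methylated, area_unmethylated) {
  if (any(area_methylated < 0, na.rm = TRUE) ||
      any(area_unmethylated < 0, na.rm = TRUE))
    abort("Peak areas must be non-negative.")
  tot <- area_methylated + area_unmethylated
  ifelse(!is.na(tot) & tot > 0, area_methylated / tot, NA_real_)
}

#' Simulation configuration
#'
#' Bundles the conditions a simulated plate emulates: the measurement model
#' is `replicate value = truth + Normal(0, sd^2)` clipped to \[0,1\], with
#' replicates failing (missing) independently, an optional subpopulation of
#' samples shifted on designated units (emulating an unknown-SNP bimodal
#' distribution), and all-NA control rows. Defaults reflect a clean run:
#' replicate noise of 0.02 (the magnitude of well-behaved triplicate
#' standard deviations) and a 5% replicate failure rate.
#'
#' @param n_samples Number of biological samples.
#' @param units Character vector of CpG unit labels, or a `cpg_units`
#'   tibble (its `desc` labels are used and warnings carried through).
#' @param truth Optional n_samples x n_units matrix of true methylation in
#'   \[0,1\]; generated if NULL (per-unit level drawn uniformly, small
#'   between-sample spread).
#' @param noise_sd Replicate noise standard deviation (default 0.02).
#' @param failure_prob Per-replicate missingness probability (default 0.05).
#' @param snp_confound_frac Fraction of samples shifted on
#'   `bimodal_units` (default 0.5).
#' @param snp_offset Shift applied to the confounded subpopulation
#'   (default 0.5).
#' @param bimodal_units Unit labels to confound (default none).
#' @param replicates Replicates per sample (default 3).
#' @param controls Control row labels (default water and gDNA).
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples, units, truth = NULL, noise_sd = 0.02,
                       failure_prob = 0.05, snp_confound_frac = 0.5,
                       snp_offset = 0.5, bimodal_units = character(0),
                       replicates = 3, controls = c("water", "gDNA"),
                       seed) {
  stopifnot(!missing(seed), n_samples >= 1, noise_sd >= 0,
            failure_prob >= 0, failure_prob <= 1,
            snp_confound_frac >= 0, snp_confound_frac <= 1)
  unit_warnings <- NULL
  if (inherits(units, "cpg_units")) {
    unit_warnings <- tibble(
      unit = units$desc,
      warning = vapply(units$warnings, function(w)
        if (length(w) == 0) NA_character_ else paste(w, collapse = ";"),
        character(1)))
    units <- units$desc
  }
  stopifnot(is.character(units), length(units) >= 1)
  if (!is.null(truth))
    stopifnot(nrow(truth) == n_samples, ncol(truth) == length(units),
              all(truth >= 0 & truth <= 1))
  structure(
    list(n_samples = n_samples, units = units, truth = truth,
         unit_warnings = unit_warnings, noise_sd = noise_sd,
         failure_prob = failure_prob,
         snp_confound_frac = snp_confound_frac, snp_offset = snp_offset,
         bimodal_units = bimodal_units, replicates = replicates,
         controls = controls, seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate an exported measurement plate
#'
#' Generates a plate grid in the same long layout [parse_export_grid()]
#' produces, with triplicate rows per sample under the plate naming
#' convention, truncated-normal replicate noise, random replicate
#' failures, optional SNP-confounded bimodal units, and all-NA control
#' rows. Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_plate`: `grid` (a `plate_grid` long
#'   tibble), `truth` (tibble `sample_id`, `unit`, `truth`), `config`.
#' @examples
#' sim <- simulate_plate(sim_config(5, c("CpG_1", "CpG_2"), seed = 1))
#' head(sim$truth)
#' @export
simulate_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  with_local_seed(cf$seed, {
    nu <- length(cf$units)
    truth <- cf$truth
    if (is.null(truth)) {
      level <- runif(nu, 0.05, 0.95)
      truth <- vapply(seq_len(nu), function(j)
        pmin(1, pmax(0, level[j] + rnorm(cf$n_samples, 0, 0.05))),
        numeric(cf$n_samples))
      truth <- matrix(truth, nrow = cf$n_samples)
    }
    if (length(cf$bimodal_units) > 0 && cf$snp_confound_frac > 0) {
      shifted <- runif(cf$n_samples) < cf$snp_confound_frac
      for (u in cf$bimodal_units) {
        j <- match(u, cf$units)
        if (is.na(j)) abort(sprintf("Unknown bimodal unit '%s'.", u))
        truth[shifted, j] <- pmin(1, pmax(0, truth[shifted, j] +
                                            cf$snp_offset))
      }
    }
    sample_ids <- sprintf("%d", seq_len(cf$n_samples) + 1000L)
    rows <- list()
    well <- 0L
    for (s in seq_len(cf$n_samples)) {
      for (r in seq_len(cf$replicates)) {
        well <- well + 1L
        v <- pmin(1, pmax(0, truth[s, ] + rnorm(nu, 0, cf$noise_sd)))
        v[runif(nu) < cf$failure_prob] <- NA_real_
        rows[[length(rows) + 1L]] <- tibble(
          label = format_sample_name(well, sample_ids[s], r),
          well = well, sample_id = sample_ids[s], replicate = r,
          unit = cf$units, value = v)
      }
    }
    for (ctrl in cf$controls) {
      rows[[length(rows) + 1L]] <- tibble(
        label = ctrl, well = NA_integer_, sample_id = ctrl,
        replicate = 1L, unit = cf$units, value = NA_real_)
    }
    grid <- bind_rows(rows)
    uw <- cf$unit_warnings %||%
      tibble(unit = cf$units, warning = NA_character_)
    grid <- structure(grid, class = c("plate_grid", class(tibble())),
                      amplicon = "simulated",
                      unit_warnings = uw, dropped_units = character(0))
    truth_tbl <- tibble(
      sample_id = rep(sample_ids, times = nu),
      unit = rep(cf$units, each = cf$n_samples),
      truth = as.vector(truth))
    structure(list(grid = grid, truth = truth_tbl, config = cf),
              class = "sim_plate")
  })
}

#' Write a plate grid in the rotated export dialect
#'
#' Serializes a long `plate_grid` back to the tab-delimited rotated layout
#' (header row of unit labels, optional `Warning` row, one row per
#' sample-replicate, missing as the literal `NA`) so that the simulator's
#' output feeds the same parser real exports do.
#'
#' @param grid A `plate_grid` long tibble.
#' @param path Output file.
#' @param provenance Optional `# `-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_export_grid <- function(grid, path, provenance = NULL) {
  units <- unique(grid$unit)
  labels <- unique(grid$label)
  wide <- tidyr::pivot_wider(grid[, c("label", "unit", "value")],
                             names_from = "unit", values_from = "value")
  wide <- wide[match(labels, wide$label), ]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  writeLines(paste(c("Sample", units), collapse = "\t"), con)
  uw <- attr(grid, "unit_warnings")
  if (!is.null(uw) && any(!is.na(uw$warning))) {
    w <- uw$warning[match(units, uw$unit)]
    writeLines(paste(c("Warning", ifelse(is.na(w), "NA", w)),
                     collapse = "\t"), con)
  }
  for (i in seq_len(nrow(wide))) {
    v <- unlist(wide[i, units])
    writeLines(paste(c(wide$label[i],
                       ifelse(is.na(v), "NA", format(v, digits = 10))),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Simulate a toy mass spectrum for a set of CpG units
#'
#' Emulates the two-peaks-per-CpG picture of the readout: every mass state
#' of every unit contributes a Gaussian peak whose area is the binomial
#' probability of that many methylated CpGs given the unit's methylation
#' fraction (per-CpG methylation independent within a unit), on top of
#' additive baseline noise. Not a physical MALDI model — no matrix effects,
#' arched baselines or (by default) sodium adducts.
#'
#' @param units A `cpg_units` tibble (needs `desc`, `n_cpg`,
#'   `mass_states`).
#' @param methylation Per-unit methylation fraction in \[0,1\].
#' @param noise_sd Baseline noise standard deviation (intensity units;
#'   default 0).
#' @param peak_width Gaussian sigma of each peak (Da; default 2).
#' @param seed Integer seed (mandatory when `noise_sd > 0`).
#' @param mass_step Axis spacing (Da; default 0.5).
#' @param adducts Add +22 Da sodium satellites at 10% area (default
#'   `FALSE`).
#' @return A list of class `toy_spectrum`: `mass`, `intensity`, `peaks`
#'   (tibble `unit`, `state`, `center`, `area`, `width`).
#' @export
simulate_spectrum <- function(units, methylation, noise_sd = 0,
                              peak_width = 2, seed = NULL,
                              mass_step = 0.5, adducts = FALSE) {
  stopifnot(nrow(units) == length(methylation),
            all(methylation >= 0 & methylation <= 1))
  if (noise_sd > 0 && is.null(seed))
    abort("`seed` is mandatory when noise is simulated.")
  peaks <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    n <- units$n_cpg[i]
    states <- units$mass_states[[i]]
    tibble(unit = units$desc[i], state = 0:n, center = states,
           area = dbinom(0:n, n, methylation[i]), width = peak_width)
  })
  if (adducts) {
    sat <- peaks |> mutate(center = .data$center + 22, area = 0.1 * .data$area)
    peaks <- bind_rows(peaks, sat)
  }
  lo <- floor(min(peaks$center)) - 50
  hi <- ceiling(max(peaks$center)) + 50
  mass <- seq(lo, hi, by = mass_step)
  intensity <- numeric(length(mass))
  for (i in seq_len(nrow(peaks))) {
    intensity <- intensity + peaks$area[i] *
      stats::dnorm(mass, peaks$center[i], peaks$width[i])
  }
  if (noise_sd > 0) {
    noise <- with_local_seed(seed, rnorm(length(mass), 0, noise_sd))
    intensity <- pmax(0, intensity + noise)
  }
  structure(list(mass = mass, intensity = intensity, peaks = peaks),
            class = "toy_spectrum")
}

#' Quantify unit methylation from a spectrum
#'
#' Integrates baseline-subtracted trapezoidal areas in a +/- `window`
#' around every expected mass state of every unit and combines them into a
#' methylation estimate: `sum(j * area_j) / (n * sum(area_j))` over states
#' `j = 0..n` (which reduces to the two-peak area ratio for one-CpG
#' units). The baseline is the median intensity away from all known peaks.
#' Estimates are flagged unreliable when two states of one unit fall within
#' one integration window of each other.
#'
#' @param spectrum A `toy_spectrum`.
#' @param units A `cpg_units` tibble.
#' @param window Half-width of the integration window (Da; default 6).
#' @return A tibble `unit`, `estimate`, `reliable`.
#' @export
integrate_and_quantify <- function(spectrum, units, window = 6) {
  mass <- spectrum$mass; intens <- spectrum$intensity
  centers <- unlist(units$mass_states)
  off_peak <- !vapply(mass, function(m)
    any(abs(m - centers) <= window + 2), logical(1))
  baseline <- if (any(off_peak)) median(intens[off_peak]) else 0
  trap <- function(lo, hi) {
    sel <- mass >= lo & mass <= hi
    if (sum(sel) < 2) return(0)
    x <- mass[sel]; y <- pmax(0, intens[sel] - baseline)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  purrr::map_dfr(seq_len(nrow(units)), function(i) {
    states <- units$mass_states[[i]]
    n <- units$n_cpg[i]
    areas <- vapply(states, function(cc) trap(cc - window, cc + window),
                    numeric(1))
    reliable <- all(diff(sort(states)) > window)
    est <- if (sum(areas) > 0)
      sum((0:n) * areas) / (n * sum(areas)) else NA_real_
    tibble(unit = units$desc[i], estimate = est, reliable = reliable)
  })
}
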