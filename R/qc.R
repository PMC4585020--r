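#' Parse and format plate sample names
#'
#' The plate naming convention is `WWW_SSSS_RR`: a zero-padded well number
#' (001–384, wells 001–012 being the first column of the 384 plate), a
#' numeric sample identifier, and the replicate number (01–03). Control
#' wells (water, unconverted genomic DNA) often carry free-text labels
#' instead; [parse_export_grid()] tolerates those, this parser does not.
#'
#' @param text Character vector of names like `"001_5186_01"`.
#' @return A tibble with columns `well`, `sample_id`, `replicate`.
#' @examples
#' parse_sample_name(c("001_5186_01", "310_5186_03"))
#' @export
parse_sample_name <- function(text) {
  parts <- strsplit(text, "_", fixed = TRUE)
  out <- lapply(seq_along(text), function(i) {
    p <- parts[[i]]
    if (length(p) != 3)
      abort(sprintf("'%s': expected three underscore-separated fields.",
                    text[i]))
    if (any(!grepl("^[0-9]+$", p)))
      abort(sprintf("'%s': non-numeric field '%s'.",
                    text[i], p[!grepl("^[0-9]+$", p)][1]))
    v <- as.integer(p)
    if (v[1] < 1 || v[1] > 384)
      abort(sprintf("'%s': well %d out of range 1-384.", text[i], v[1]))
    if (v[3] < 1 || v[3] > 3)
      abort(sprintf("'%s': replicate %d out of range 1-3.", text[i], v[3]))
    v
  })
  m <- do.call(rbind, out)
  tibble(well = m[, 1], sample_id = m[, 2], replicate = m[, 3])
}

#' @rdname parse_sample_name
#' @param well,sample_id,replicate Integer vectors.
#' @export
format_sample_name <- function(well, sample_id, replicate) {
  sprintf("%03d_%s_%02d", as.integer(well), as.character(sample_id),
          as.integer(replicate))
}

is_convention_name <- function(text) {
  grepl("^[0-9]{1,3}_[0-9]+_[0-9]{1,2}$", text)
}

#' Parse an exported measurement grid
#'
#' Reads the rotated tab-delimited export: first header row carries the CpG
#' unit labels, an optional second row labelled `Warning` carries per-unit
#' warning codes, and every following row is one sample-replicate with
#' methylation fractions in \[0,1\] (`NA` or empty when missing). Columns
#' that are entirely missing belong to other amplicons multiplexed on the
#' plate and are dropped (and logged as an attribute).
#'
#' @param file Path to the exported grid, or a character vector of lines.
#' @param amplicon_name Optional name; defaults to the file stem.
#' @return A long tibble of class `plate_grid` with columns `label`,
#'   `well`, `sample_id` (character key), `replicate`, `unit`, `value`;
#'   attributes `amplicon`, `unit_warnings` (tibble unit/warning),
#'   `dropped_units`.
#' @export
parse_export_grid <- function(file, amplicon_name = NULL) {
  if (length(file) == 1 && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    amplicon_name <- amplicon_name %||%
      sub("\\.[^.]*$", "", basename(file))
  } else {
    lines <- file
    amplicon_name <- amplicon_name %||% "amplicon"
  }
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) abort("Empty or headerless export grid.")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  units <- header[-1]
  if (length(units) == 0) abort("Export grid has no unit columns.")

  row_i <- 2L
  warnings_row <- NULL
  if (tolower(trimws(cells[[2]][1])) == "warning") {
    warnings_row <- cells[[2]][-1]
    length(warnings_row) <- length(units)
    warnings_row[warnings_row %in% c("", "NA")] <- NA_character_
    row_i <- 3L
  }
  if (row_i > length(cells)) abort("Export grid has no sample rows.")

  body <- cells[row_i:length(cells)]
  labels <- vapply(body, function(r) trimws(r[1]), character(1))
  vals <- lapply(body, function(r) {
    v <- r[-1]
    length(v) <- length(units)
    v[v %in% c("", "NA")] <- NA
    suppressWarnings(num <- as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0)
      abort(sprintf("Non-numeric value '%s' for sample '%s', unit '%s'.",
                    v[bad[1]], r[1], units[bad[1]]))
    num
  })
  mat <- do.call(rbind, vals)
  out_of_range <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
  if (nrow(out_of_range) > 0)
    abort(sprintf(
      "Value %g outside [0,1] for sample '%s', unit '%s'.",
      mat[out_of_range[1, 1], out_of_range[1, 2]],
      labels[out_of_range[1, 1]], units[out_of_range[1, 2]]))

  conv <- is_convention_name(labels)
  well <- rep(NA_integer_, length(labels))
  sample_id <- labels
  replicate <- rep(NA_integer_, length(labels))
  if (any(conv)) {
    parsed <- parse_sample_name(labels[conv])
    well[conv] <- parsed$well
    sample_id[conv] <- as.character(parsed$sample_id)
    replicate[conv] <- parsed$replicate
  }
  # non-convention labels (controls): replicate = occurrence order
  if (any(!conv)) {
    replicate[!conv] <- stats::ave(seq_along(labels), labels,
                                   FUN = seq_along)[!conv]
  }
  key <- paste(sample_id, replicate, sep = "\r")
  if (anyDuplicated(key))
    abort(sprintf("Duplicate sample/replicate row: '%s'.",
                  labels[duplicated(key)][1]))

  # drop all-NA columns (other amplicons on the same plate)
  all_na <- apply(mat, 2, function(x) all(is.na(x)))
  dropped <- units[all_na]
  keep <- which(!all_na)
  grid <- tibble(
    label = rep(labels, times = length(keep)),
    well = rep(well, times = length(keep)),
    sample_id = rep(sample_id, times = length(keep)),
    replicate = rep(replicate, times = length(keep)),
    unit = rep(units[keep], each = length(labels)),
    value = as.vector(mat[, keep, drop = FALSE]))
  uw <- tibble(unit = units,
               warning = if (is.null(warnings_row))
                 NA_character_ else warnings_row)
  structure(grid, class = c("plate_grid", class(grid)),
            amplicon = amplicon_name,
            unit_warnings = uw[!all_na | !is.na(uw$warning), ],
            dropped_units = dropped)
}

#' Collapse triplicate measurements
#'
#' Applies the replicate-level cleaning rules, then averages: a (sample,
#' unit) cell is set missing when fewer than `min_replicates` replicates
#' succeeded, or when the replicate standard deviation (n-1 denominator,
#' over the non-missing replicates) is `sd_cutoff` or larger; otherwise the
#' cell is the arithmetic mean of the non-missing replicates.
#'
#' @param grid A `plate_grid` (long tibble from [parse_export_grid()] or
#'   [simulate_plate()]).
#' @param sd_cutoff Replicate standard deviation at or above which a cell is
#'   discarded (fraction methylation; default 0.1, i.e. 10 percentage
#'   points).
#' @param min_replicates Minimum successful replicates per cell (default 2).
#' @return A tibble of class `collapsed_grid`: `sample_id`, `unit`,
#'   `n_obs`, `rep_sd`, `value` (mean or NA), `reason` (NA when retained).
#'   Grid attributes (`amplicon`, `unit_warnings`) are carried over.
#' @export
collapse_replicates <- function(grid, sd_cutoff = 0.1, min_replicates = 2) {
  stopifnot(all(c("sample_id", "unit", "value") %in% names(grid)))
  out <- grid |>
    group_by(.data$sample_id, .data$unit) |>
    summarise(
      n_obs = sum(!is.na(.data$value)),
      rep_sd = if (sum(!is.na(.data$value)) >= 2)
        sd(.data$value, na.rm = TRUE) else NA_real_,
      mean_value = if (sum(!is.na(.data$value)) > 0)
        mean(.data$value, na.rm = TRUE) else NA_real_,
      .groups = "drop") |>
    mutate(
      reason = dplyr::case_when(
        .data$n_obs < min_replicates ~ "too_few_replicates",
        .data$rep_sd >= sd_cutoff ~ "replicate_sd",
        TRUE ~ NA_character_),
      value = ifelse(is.na(.data$reason), .data$mean_value, NA_real_)) |>
    select("sample_id", "unit", "n_obs", "rep_sd", "value", "reason")
  structure(out, class = c("collapsed_grid", class(tibble())),
            amplicon = attr(grid, "amplicon"),
            unit_warnings = attr(grid, "unit_warnings"),
            sd_cutoff = sd_cutoff, min_replicates = min_replicates)
}

classify_unit_warning <- function(w) {
  dplyr::case_when(
    is.na(w) ~ NA_character_,
    grepl("^D(_|$|[0-9])", w) | w == "DUP" ~ "DUP",
    grepl("^OL", w) | w == "OVERLAP" ~ "OVERLAP",
    grepl("^L_?mass$", w, ignore.case = TRUE) | w == "L_MASS" ~ "L_MASS",
    grepl("^H_?mass$", w, ignore.case = TRUE) | w == "H_MASS" ~ "H_MASS",
    grepl("^SN", w) | w == "SILENT_OVERLAP" ~ "SILENT_OVERLAP",
    TRUE ~ w)
}

#' Unit-level quality filtering
#'
#' Applies the unit-level cleaning rules to a collapsed matrix:
#' * remove units whose success rate over biological samples is below
#'   `success_cutoff` (default 80%);
#' * remove units carrying a duplicate-mass (`D`) or mass-overlap (`OL`)
#'   warning when `remove_overlaps` is `TRUE` — their signal cannot be
#'   assigned uniquely;
#' * remove units overlapping a common SNP (`snp_units`).
#'
#' Control samples (water, unconverted gDNA, or any id in `exclude`) are
#' excluded from the success-rate denominator and from the output. Units
#' with a silent-fragment overlap warning (`SN` class) are annotated but
#' retained; they usually fall to the success-rate rule when the overlap
#' actually hurts. Every removal is logged.
#'
#' @param collapsed A `collapsed_grid` from [collapse_replicates()], or any
#'   tibble with `sample_id`, `unit`, `value`.
#' @param unit_warnings Optional tibble `unit`/`warning`; defaults to the
#'   attribute carried by `collapsed`.
#' @param success_cutoff Minimum success rate (default 0.8).
#' @param remove_overlaps Remove `D`/`OL` units (default `TRUE`).
#' @param snp_units Character vector of unit labels overlapping a common
#'   SNP.
#' @param exclude Sample ids treated as controls.
#' @return An object of class `qc_result`: list with `matrix` (long clean
#'   tibble), `success_rates`, `exclusions` (log tibble), `params`.
#' @export
filter_units <- function(collapsed, unit_warnings = NULL,
                         success_cutoff = 0.8, remove_overlaps = TRUE,
                         snp_units = character(0),
                         exclude = c("water", "gDNA")) {
  uw <- unit_warnings %||% attr(collapsed, "unit_warnings") %||%
    tibble(unit = unique(collapsed$unit), warning = NA_character_)
  uw$class <- classify_unit_warning(uw$warning)

  excl_log <- tibble(scope = character(), id = character(),
                     rule = character(), detail = character())
  ctrl <- collapsed$sample_id %in% exclude
  if (any(ctrl)) {
    excl_log <- bind_rows(excl_log, tibble(
      scope = "sample", id = unique(collapsed$sample_id[ctrl]),
      rule = "control_sample",
      detail = "excluded from success rates and output"))
  }
  bio <- collapsed[!ctrl, , drop = FALSE]

  rates <- bio |>
    group_by(.data$unit) |>
    summarise(n_samples = dplyr::n_distinct(.data$sample_id),
              n_success = sum(!is.na(.data$value)),
              success_rate = .data$n_success / .data$n_samples,
              .groups = "drop") |>
    left_join(uw[, c("unit", "warning", "class")], by = "unit")

  drop_units <- character(0)
  for (i in seq_len(nrow(rates))) {
    u <- rates$unit[i]
    if (remove_overlaps && !is.na(rates$class[i]) &&
        rates$class[i] %in% c("DUP", "OVERLAP")) {
      drop_units <- c(drop_units, u)
      excl_log <- bind_rows(excl_log, tibble(
        scope = "unit", id = u, rule = "mass_overlap",
        detail = sprintf("warning '%s'", rates$warning[i])))
    } else if (u %in% snp_units) {
      drop_units <- c(drop_units, u)
      excl_log <- bind_rows(excl_log, tibble(
        scope = "unit", id = u, rule = "snp_overlap",
        detail = "common SNP in fragment"))
    } else if (rates$success_rate[i] < success_cutoff) {
      drop_units <- c(drop_units, u)
      excl_log <- bind_rows(excl_log, tibble(
        scope = "unit", id = u, rule = "success_rate",
        detail = sprintf("%d/%d = %.0f%% < %.0f%%",
                         rates$n_success[i], rates$n_samples[i],
                         100 * rates$success_rate[i],
                         100 * success_cutoff)))
    }
  }
  clean <- bio[!bio$unit %in% drop_units,
               intersect(c("sample_id", "unit", "value"), names(bio))]
  structure(
    list(matrix = as_tibble(clean),
         success_rates = rates,
         exclusions = excl_log,
         params = list(success_cutoff = success_cutoff,
                       remove_overlaps = remove_overlaps,
                       snp_units = snp_units, exclude = exclude)),
    class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d units retained of %d; %d sample(s) excluded as controls\n",
              length(unique(x$matrix$unit)), nrow(x$success_rates),
              sum(x$exclusions$rule == "control_sample")))
  print(as.data.frame(x$success_rates[, c("unit", "success_rate",
                                          "warning")]), row.names = FALSE)
  invisible(x)
}

#' @describeIn filter_units Clean long matrix (one row per retained sample
#'   and unit).
#' @param x A `qc_result`.
#' @param ... Unused.
#' @export
tidy.qc_result <- function(x, ...) x$matrix

#' @describeIn filter_units One-row summary of the QC run.
#' @export
glance.qc_result <- function(x, ...) {
  tibble(
    n_units_in = nrow(x$success_rates),
    n_units_out = length(unique(x$matrix$unit)),
    n_samples = length(unique(x$matrix$sample_id)),
    n_cells_out = sum(!is.na(x$matrix$value)),
    min_success_rate = min(x$success_rates$success_rate),
    success_cutoff = x$params$success_cutoff)
}

#' Flag a bi- or tri-modal methylation distribution
#'
#' A clearly multimodal distribution of collapsed methylation values across
#' samples indicates that an (unknown) SNP in the fragment confounds the
#' measurement. One- and two-component Gaussian mixtures are fitted by EM
#' (via \pkg{mclust}) and the unit is flagged when the two-component model
#' wins on BIC, the component means differ by more than 0.2, and both
#' mixing weights exceed 0.2. The flag is advisory: downstream removal is a
#' judgment call (see the `drop_multimodal` option of the pipeline).
#'
#' @param values Numeric vector of per-sample methylation fractions for one
#'   unit (NAs dropped). Fewer than 20 values is not assessable.
#' @return A one-row tibble: `n`, `assessable`, `multimodal`,
#'   `delta_mean`, `min_weight`, `dbic` (BIC(2) - BIC(1), positive favours
#'   two components), `note`.
#' @importFrom mclust Mclust mclustBIC
#' @export
flag_multimodal <- function(values) {
  x <- values[!is.na(values)]
  res <- tibble(n = length(x), assessable = FALSE, multimodal = FALSE,
                delta_mean = NA_real_, min_weight = NA_real_,
                dbic = NA_real_, note = NA_character_)
  if (length(x) < 20) {
    res$note <- "fewer than 20 values; not assessable"
    return(res)
  }
  if (sd(x) < 1e-8) {
    res$assessable <- TRUE
    res$note <- "degenerate (constant) distribution"
    return(res)
  }
  fit <- mclust::Mclust(x, G = 1:2, verbose = FALSE)
  res$assessable <- TRUE
  bics <- apply(fit$BIC, 1, max, na.rm = TRUE)  # per-G best model
  res$dbic <- unname(bics["2"] - bics["1"])
  if (fit$G == 2) {
    mu <- as.numeric(fit$parameters$mean)
    pro <- fit$parameters$pro
    res$delta_mean <- abs(diff(mu))
    res$min_weight <- min(pro)
    res$multimodal <- res$dbic > 0 && res$delta_mean > 0.2 &&
      res$min_weight > 0.2
  }
  res
}

#' Per-well bisulfite conversion score
#'
#' A qualitative score of conversion completeness from the signal observed
#' at a conversion-control fragment's converted mass and its unconverted
#' (+16 Da per retained cytosine) satellite: `100 * unconverted /
#' (converted + unconverted)`, averaged over the control fragments of a
#' well. Values below 2 indicate adequate conversion; higher values flag a
#' sample whose bisulfite reaction may have been incomplete. This
#' intensity-ratio definition is an explicit stand-in for the reference
#' per-well conversion metric, whose exact formula is unpublished.
#'
#' @param intensities A tibble with columns `well`, `converted`,
#'   `unconverted` (one row per control fragment per well), or two numeric
#'   vectors via `converted`/`unconverted`.
#' @param converted,unconverted Alternative vector interface.
#' @return With a tibble input: tibble `well`, `score` (NA when no
#'   signal). With vectors: a numeric vector of scores.
#' @examples
#' conversion_score(converted = 99, unconverted = 1)
#' @export
conversion_score <- function(intensities = NULL, converted = NULL,
                             unconverted = NULL) {
  score1 <- function(cv, uc) {
    if (any(cv < 0, na.rm = TRUE) || any(uc < 0, na.rm = TRUE))
      abort("Intensities must be non-negative.")
    tot <- cv + uc
    ifelse(!is.na(tot) & tot > 0, 100 * uc / tot, NA_real_)
  }
  if (is.null(intensities)) return(score1(converted, unconverted))
  stopifnot(all(c("well", "converted", "unconverted") %in%
                  names(intensities)))
  intensities |>
    mutate(s = score1(.data$converted, .data$unconverted)) |>
    group_by(.data$well) |>
    summarise(score = if (all(is.na(.data$s))) NA_real_
              else mean(.data$s, na.rm = TRUE), .groups = "drop")
}

#' Design a randomized 384-well triplicate plate
#'
#' Every sample (and every control) occupies `replicates` distinct wells;
#' with triplicates on 384 wells and the two standard PCR controls (water
#' and unconverted gDNA) the capacity is 126 biological samples. Slot
#' positions are randomized with the given seed, so the layout is
#' reproducible.
#'
#' @param sample_ids Vector of sample identifiers (numeric recommended —
#'   the plate software sorts text poorly).
#' @param seed Integer seed for the layout randomization (mandatory).
#' @param n_wells Plate size (default 384).
#' @param replicates Measurements per sample (default 3).
#' @param controls Control labels, one slot each (default water and
#'   unconverted gDNA).
#' @return A tibble `well`, `sample_id`, `replicate`, `label`,
#'   `is_control`, sorted by well; empty wells are absent.
#' @examples
#' design_plate(1:5, seed = 1)
#' @export
design_plate <- function(sample_ids, seed, n_wells = 384, replicates = 3,
                         controls = c("water", "gDNA")) {
  stopifnot(!missing(seed))
  capacity <- n_wells %/% replicates - length(controls)
  if (length(sample_ids) > capacity)
    abort(sprintf("Too many samples: %d exceed the capacity of %d (%d wells / %d replicates - %d control slots).",
                  length(sample_ids), capacity, n_wells, replicates,
                  length(controls)))
  entities <- c(as.character(sample_ids), controls)
  is_ctrl <- c(rep(FALSE, length(sample_ids)), rep(TRUE, length(controls)))
  long <- tibble(
    sample_id = rep(entities, each = replicates),
    replicate = rep(seq_len(replicates), times = length(entities)),
    is_control = rep(is_ctrl, each = replicates))
  wells <- with_local_seed(seed, sample(n_wells, nrow(long)))
  long$well <- wells
  long <- arrange(long, .data$well)
  long$label <- format_sample_name(long$well, long$sample_id,
                                   long$replicate)
  long[, c("well", "sample_id", "replicate", "label", "is_control")]
}

#' Plate capacity
#' @inheritParams design_plate
#' @return Number of biological sample slots.
#' @export
plate_capacity <- function(n_wells = 384, replicates = 3,
                           controls = c("water", "gDNA")) {
  n_wells %/% replicates - length(controls)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
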