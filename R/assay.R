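#' Enumerate CpG units of an amplicon
#'
#' A CpG unit is a cleavage fragment of the (fully unmethylated)
#' fragmentation that contains one or more CpG sites — the smallest entity
#' whose methylation the mass readout can report. Each unit has `n_cpg + 1`
#' mass states (0 .. n methylated CpGs, 16 Da apart). Units whose states
#' stray outside the measurable window are flagged `L_MASS` / `H_MASS`;
#' units whose fragment overlaps a masked (SNP/repeat) position are flagged
#' via `snp_overlap`.
#'
#' @param amplicon An `annotated_amplicon` or DNA string.
#' @param model A [mass_model()].
#' @return A tibble of class `cpg_units`, one row per unit in CpG-site
#'   order: `name` (`CpG_Unit_<sites>`), `desc` (`CpG_<sites>`, dot-joined
#'   site numbers), `fragment`, `fwd_start`, `fwd_end`, `n_cpg`,
#'   `cpg_sites` (list), `base_mass`, `mass_states` (list), `warnings`
#'   (list), `snp_overlap`, `nearest_da`, `measurable`.
#' @examples
#' units <- enumerate_cpg_units("ACTTGGGACGCCTCAGGATTTTTTTTTTAACGATTTT")
#' units[, c("name", "base_mass", "measurable")]
#' @export
enumerate_cpg_units <- function(amplicon, model = mass_model()) {
  if (!inherits(amplicon, "annotated_amplicon"))
    amplicon <- parse_annotated_sequence(amplicon_sequence(amplicon))
  frags <- fragment_amplicon(amplicon, methylation = FALSE, model = model)
  cf <- dplyr::filter(frags, .data$n_cpg > 0)
  if (nrow(cf) == 0) {
    out <- tibble(name = character(), desc = character(),
                  fragment = integer(), fwd_start = integer(),
                  fwd_end = integer(), n_cpg = integer(),
                  cpg_sites = list(), base_mass = numeric(),
                  mass_states = list(), warnings = list(),
                  snp_overlap = logical(), nearest_da = numeric(),
                  measurable = logical())
    return(structure(out, class = c("cpg_units", class(out)),
                     amplicon = amplicon$name, model = model))
  }
  cf <- cf[order(vapply(cf$cpg_sites, min, integer(1))), ]
  label <- vapply(cf$cpg_sites, function(k) paste(k, collapse = "."), "")
  states <- lapply(seq_len(nrow(cf)), function(i)
    round(cf$base_mass[i] + model$methylation_shift * 0:cf$n_cpg[i], 3))
  warn <- lapply(seq_len(nrow(cf)), function(i) {
    w <- character(0)
    if (any(states[[i]] < model$min_mass)) w <- c(w, "L_MASS")
    if (any(states[[i]] > model$max_mass)) w <- c(w, "H_MASS")
    w
  })
  masked <- amplicon$masked_positions
  snp <- vapply(seq_len(nrow(cf)), function(i)
    any(seq(cf$fwd_start[i], cf$fwd_end[i]) %in% masked), logical(1))
  out <- tibble(
    name = paste0("CpG_Unit_", label),
    desc = paste0("CpG_", label),
    fragment = cf$fragment,
    fwd_start = cf$fwd_start, fwd_end = cf$fwd_end,
    n_cpg = cf$n_cpg, cpg_sites = cf$cpg_sites,
    base_mass = cf$base_mass, mass_states = states,
    warnings = warn, snp_overlap = snp,
    nearest_da = NA_real_,
    measurable = !vapply(warn, function(w)
      any(w %in% c("L_MASS", "H_MASS", "DUP", "OVERLAP")), logical(1)))
  structure(out, class = c("cpg_units", class(out)),
            amplicon = amplicon$name, model = model)
}

#' Detect mass collisions among CpG units and silent fragments
#'
#' Two peaks closer than `collision_tolerance` cannot be told apart:
#' * `DUP` — another unit has the same number of CpGs and all mass states
#'   pairwise identical within tolerance (same composition);
#' * `OVERLAP` — any state of this unit collides with any state of another
#'   unit;
#' * `SILENT_OVERLAP` — any state collides with a CpG-free (silent)
#'   fragment's mass;
#' * `NEAR` — the smallest distance to any other fragment mass is below
#'   `near_collision_threshold` but above tolerance; the distance is
#'   recorded in `nearest_da` (NA when nothing is that close).
#'
#' `DUP` and `OVERLAP` make a unit unusable (the signal cannot be assigned
#' uniquely); `NEAR` neighbours tend to inflate triplicate variance.
#'
#' @param units A `cpg_units` tibble.
#' @param silent_fragments A `cleave_fragments` tibble restricted to
#'   CpG-free fragments (or the full fragmentation; CpG rows are ignored).
#' @param model A [mass_model()].
#' @return `units` with `warnings`, `nearest_da` and `measurable` updated.
#' @export
detect_collisions <- function(units, silent_fragments, model = mass_model()) {
  n <- nrow(units)
  if (n == 0) return(units)
  sil <- silent_fragments[silent_fragments$n_cpg == 0, , drop = FALSE]
  sil_mass <- sil$base_mass
  tol <- model$collision_tolerance
  near <- model$near_collision_threshold

  warnings <- units$warnings
  nearest <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    si <- units$mass_states[[i]]
    w <- warnings[[i]]
    dmin <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      sj <- units$mass_states[[j]]
      d <- abs(outer(si, sj, "-"))
      if (units$n_cpg[i] == units$n_cpg[j] &&
          all(abs(si - sj) <= tol))
        w <- union(w, "DUP")
      if (any(d <= tol)) w <- union(w, "OVERLAP")
      dmin <- min(dmin, d)
    }
    if (length(sil_mass) > 0) {
      d <- abs(outer(si, sil_mass, "-"))
      if (any(d <= tol)) w <- union(w, "SILENT_OVERLAP")
      dmin <- min(dmin, d)
    }
    if (is.finite(dmin) && dmin > tol && dmin < near) {
      w <- union(w, "NEAR")
      nearest[i] <- round(dmin, 3)
    }
    warnings[[i]] <- w
  }
  units$warnings <- warnings
  units$nearest_da <- nearest
  units$measurable <- !vapply(warnings, function(w)
    any(w %in% c("L_MASS", "H_MASS", "DUP", "OVERLAP")), logical(1))
  units
}

#' Find bisulfite conversion-control fragments
#'
#' A conversion-control fragment is CpG-free, witnesses at least one
#' converted non-CpG cytosine, sits inside the measurable mass window, and
#' its unconverted satellites (+16 Da per retained cytosine) do not collide
#' with any other fragment mass. Residual signal at those satellites in a
#' real spectrum indicates incomplete bisulfite conversion.
#'
#' @param fragments A `cleave_fragments` tibble from the unmethylated
#'   fragmentation (all fragments, CpG-containing and silent).
#' @param model A [mass_model()].
#' @return The qualifying rows of `fragments`, with a list-column
#'   `unconverted_masses`.
#' @export
find_conversion_controls <- function(fragments, model = mass_model()) {
  cand <- fragments[fragments$converted_c >= 1 & fragments$n_cpg == 0 &
                      fragments$base_mass >= model$min_mass &
                      fragments$base_mass <= model$max_mass, , drop = FALSE]
  if (nrow(cand) == 0) {
    cand$unconverted_masses <- list()
    return(cand)
  }
  # every mass any fragment can present (all methylation states of units)
  all_states <- unlist(lapply(seq_len(nrow(fragments)), function(i)
    fragments$base_mass[i] +
      model$methylation_shift * 0:fragments$n_cpg[i]))
  keep <- logical(nrow(cand))
  variants <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    v <- cand$base_mass[i] +
      model$methylation_shift * seq_len(cand$converted_c[i])
    others <- setdiff_tol(all_states, cand$base_mass[i])
    keep[i] <- all(vapply(v, function(m)
      all(abs(others - m) > model$collision_tolerance), logical(1)))
    variants[[i]] <- round(v, 3)
  }
  cand <- cand[keep, , drop = FALSE]
  cand$unconverted_masses <- variants[keep]
  cand
}

# drop ONE occurrence of `value` from x (the candidate's own base mass)
setdiff_tol <- function(x, value) {
  hit <- which(abs(x - value) <= 1e-9)
  if (length(hit) > 0) x <- x[-hit[1]]
  x
}

#' Evaluate an amplicon design (the "T report")
#'
#' Runs the full in-silico evaluation: fragmentation of the unmethylated
#' amplicon, CpG-unit enumeration, mass-window and collision warnings, and
#' conversion-control detection, summarised in a verdict. The tabular part
#' ([report_table()]) lists the units whose masses fall inside the window,
#' with their base mass, contained sites, and nearest-neighbour distance
#' when anything lies within the near-collision threshold.
#'
#' @param amplicon An `annotated_amplicon` or DNA string.
#' @param model A [mass_model()].
#' @return An object of class `assay_report`: list with `amplicon`,
#'   `model`, `fragments`, `units`, `controls`, `measurable_count`,
#'   `verdict`.
#' @examples
#' rep <- amplicon_report("ACTTGGGACGCCTCAGGATTTTTTTTTTAACGATTTT")
#' rep$measurable_count
#' @export
amplicon_report <- function(amplicon, model = mass_model()) {
  if (!inherits(amplicon, "annotated_amplicon"))
    amplicon <- parse_annotated_sequence(amplicon_sequence(amplicon))
  frags <- fragment_amplicon(amplicon, methylation = FALSE, model = model)
  units <- enumerate_cpg_units(amplicon, model = model)
  units <- detect_collisions(units, frags, model = model)
  controls <- find_conversion_controls(frags, model = model)
  n_meas <- sum(units$measurable)
  verdict <- sprintf(
    "%d of %d CpG units measurable; %d conversion-control fragment(s); %d SNP-flagged unit(s)",
    n_meas, nrow(units), nrow(controls), sum(units$snp_overlap))
  structure(
    list(amplicon = amplicon, model = model, fragments = frags,
         units = units, controls = controls,
         measurable_count = n_meas, verdict = verdict),
    class = "assay_report")
}

#' @export
print.assay_report <- function(x, ...) {
  cat(sprintf("<assay_report> %s (%d bp, %d CpG sites)\n",
              x$amplicon$name, nchar(x$amplicon$sequence),
              length(x$amplicon$cpg_sites)))
  cat(" ", x$verdict, "\n")
  tab <- report_table(x)
  if (nrow(tab) > 0) print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Tabular T report
#'
#' The unit table in its exchange layout: `Name`, `Base mass`, `Desc`,
#' `< 15.9 Da` — one row per CpG unit whose mass states fall inside the
#' measurable window.
#' @param report An `assay_report`.
#' @return A tibble.
#' @export
report_table <- function(report) {
  u <- report$units
  inwin <- !vapply(u$warnings, function(w)
    any(w %in% c("L_MASS", "H_MASS")), logical(1))
  u <- u[inwin, , drop = FALSE]
  tibble(Name = u$name,
         `Base mass` = u$base_mass,
         Desc = u$desc,
         `< 15.9 Da` = u$nearest_da)
}

#' Write a T report to a tab-delimited file
#'
#' @param report An `assay_report`.
#' @param path Output file.
#' @param provenance Optional character vector of `# `-prefixed header
#'   lines written before the table.
#' @return `path`, invisibly.
#' @export
write_t_report <- function(report, path, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(provenance, con)
  tab <- report_table(report)
  writeLines(paste(names(tab), collapse = "\t"), con)
  if (nrow(tab) > 0) {
    lines <- apply(tab, 1, function(r) {
      r <- ifelse(is.na(r), "NA", trimws(as.character(r)))
      paste(r, collapse = "\t")
    })
    writeLines(lines, con)
  }
  invisible(path)
}

#' @describeIn amplicon_report One row per CpG unit with warnings flattened
#'   to a semicolon-joined string.
#' @param x An `assay_report`.
#' @param ... Unused.
#' @export
tidy.assay_report <- function(x, ...) {
  u <- x$units
  tibble(
    amplicon = x$amplicon$name,
    name = u$name, desc = u$desc,
    n_cpg = u$n_cpg,
    base_mass = u$base_mass,
    warnings = vapply(u$warnings, function(w)
      paste(w, collapse = ";"), character(1)),
    snp_overlap = u$snp_overlap,
    nearest_da = u$nearest_da,
    measurable = u$measurable)
}

#' @describeIn amplicon_report One-row design summary.
#' @export
glance.assay_report <- function(x, ...) {
  tibble(
    amplicon = x$amplicon$name,
    length_bp = nchar(x$amplicon$sequence),
    n_cpg_sites = length(x$amplicon$cpg_sites),
    n_units = nrow(x$units),
    n_measurable = x$measurable_count,
    n_conversion_controls = nrow(x$controls),
    n_snp_flagged = sum(x$units$snp_overlap))
}
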