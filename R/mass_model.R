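#' Mass model for T-cleavage fragments
#'
#' The mass of a cleavage fragment is the sum of the average in-chain masses
#' of its transcript residues plus a constant terminal-group mass added once
#' per fragment, plus 16 Da for every methylated CpG the fragment carries.
#' The T-reaction transcript incorporates ribonucleotides A, G, U and
#' *deoxy*-C (which is what makes the RNase cleavage uracil-specific), so C
#' is carried at its deoxy in-chain mass.
#'
#' The +16 Da methylation shift is not an independent constant but a
#' consequence of the chemistry: a methylation-protected cytosine on the
#' forward strand templates a G in the reverse-strand transcript where an
#' unmethylated (converted) cytosine would have templated an A, and
#' G and A differ by 16.00 Da in-chain.
#'
#' The terminal-group constant `kappa` was calibrated once against published
#' reference fragment masses of a leptin-promoter amplicon and is frozen at
#' 19.031 Da; [calibrate_kappa()] re-derives it from any set of known
#' composition/mass pairs.
#'
#' @param residue_mass Named numeric: average in-chain residue mass (Da) for
#'   transcript bases `A`, `C`, `G`, `U`.
#' @param kappa Terminal-group constant (Da), added once per fragment.
#' @param methylation_shift Mass added per methylated CpG (Da).
#' @param min_mass,max_mass Measurable mass window of the spectrometer (Da).
#' @param collision_tolerance Two masses closer than this are treated as the
#'   same peak (Da).
#' @param near_collision_threshold Masses closer than this (but farther than
#'   `collision_tolerance`) are flagged as near neighbours (Da); near
#'   neighbours inflate triplicate variance even when the peaks are nominally
#'   distinct.
#' @param adduct_shift Sodium-adduct satellite offset (Da); informational,
#'   used only by the optional adduct simulation.
#'
#' @return An object of class `mass_model`.
#' @examples
#' m <- mass_model()
#' fragment_mass(c(A = 5, C = 1, U = 1), 0, m)
#' @export
mass_model <- function(residue_mass = c(A = 329.21, C = 289.18,
                                        G = 345.21, U = 306.17),
                       kappa = 19.031,
                       methylation_shift = 16.00,
                       min_mass = 1500,
                       max_mass = 7000,
                       collision_tolerance = 1.0,
                       near_collision_threshold = 15.9,
                       adduct_shift = 22) {
  stopifnot(is.numeric(residue_mass),
            all(c("A", "C", "G", "U") %in% names(residue_mass)))
  residue_mass <- residue_mass[c("A", "C", "G", "U")]
  if (any(residue_mass <= 0) || kappa <= 0)
    abort("All residue masses and kappa must be strictly positive.")
  if (min_mass >= max_mass)
    abort("`min_mass` must be smaller than `max_mass`.")
  if (abs(methylation_shift -
          (residue_mass[["G"]] - residue_mass[["A"]])) > 0.05)
    abort(paste0(
      "`methylation_shift` is inconsistent with the residue masses: ",
      "a methylated CpG swaps a transcript A for a G, so the shift must ",
      "equal residue_mass[G] - residue_mass[A] within 0.05 Da."))
  structure(
    list(residue_mass = residue_mass, kappa = kappa,
         methylation_shift = methylation_shift,
         min_mass = min_mass, max_mass = max_mass,
         collision_tolerance = collision_tolerance,
         near_collision_threshold = near_collision_threshold,
         adduct_shift = adduct_shift),
    class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat("<mass_model>\n")
  cat("  residue masses (Da):",
      paste(names(x$residue_mass), format(x$residue_mass), sep = "=",
            collapse = "  "), "\n")
  cat(sprintf("  terminal constant kappa: %.3f Da\n", x$kappa))
  cat(sprintf("  methylation shift: %.2f Da per methylated CpG\n",
              x$methylation_shift))
  cat(sprintf("  mass window: [%g, %g] Da\n", x$min_mass, x$max_mass))
  cat(sprintf("  collision / near thresholds: %g / %g Da\n",
              x$collision_tolerance, x$near_collision_threshold))
  invisible(x)
}

#' Fragment mass from base composition
#'
#' @param composition Named non-negative integer counts over transcript bases
#'   `A`, `C`, `G`, `U` (missing names count as zero).
#' @param n_methylated Number of methylated CpGs carried by the fragment.
#' @param model A [mass_model()].
#' @return Mass in Da, rounded to 3 decimals.
#' @examples
#' fragment_mass(c(A = 4, C = 3, U = 1), 0, mass_model())
#' @export
fragment_mass <- function(composition, n_methylated = 0, model = mass_model()) {
  if (any(composition < 0)) abort("Base counts must be non-negative.")
  if (n_methylated < 0) abort("`n_methylated` must be non-negative.")
  bad <- setdiff(names(composition), c("A", "C", "G", "U"))
  if (length(bad) > 0)
    abort(paste0("Unknown transcript base(s): ", paste(bad, collapse = ", ")))
  counts <- setNames(numeric(4), c("A", "C", "G", "U"))
  counts[names(composition)] <- composition
  round(sum(counts * model$residue_mass) + model$kappa +
          n_methylated * model$methylation_shift, 3)
}

#' Re-derive the terminal-group constant from known fragments
#'
#' Given reference fragments of known base composition and observed mass,
#' returns the least-squares terminal constant (the mean of observed minus
#' residue-sum masses). Used once to pin the default `kappa`; exported so a
#' different instrument calibration can be folded in.
#'
#' @param compositions List of named count vectors (one per fragment).
#' @param observed_masses Numeric vector of observed fragment masses (Da),
#'   at zero methylation.
#' @param model A [mass_model()] supplying residue masses.
#' @return A list with `kappa` (the estimate) and `spread` (max minus min of
#'   the per-fragment estimates, a self-consistency check).
#' @export
calibrate_kappa <- function(compositions, observed_masses,
                            model = mass_model()) {
  stopifnot(length(compositions) == length(observed_masses))
  per <- vapply(seq_along(compositions), function(i) {
    counts <- setNames(numeric(4), c("A", "C", "G", "U"))
    counts[names(compositions[[i]])] <- compositions[[i]]
    observed_masses[[i]] - sum(counts * model$residue_mass)
  }, numeric(1))
  list(kappa = mean(per), spread = max(per) - min(per), per_fragment = per)
}

base_composition <- function(seq) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- setNames(integer(4), c("A", "C", "G", "U"))
  tab <- table(factor(b, levels = c("A", "C", "G", "U")))
  counts[names(tab)] <- as.integer(tab)
  counts
}
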