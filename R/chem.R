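#' Bisulfite conversion in silico
#'
#' Bisulfite treatment converts every unmethylated cytosine to uracil (read
#' as thymine after PCR) while 5-methyl-cytosine is protected. In the CpG
#' context the methylation state decides the outcome; cytosines outside a
#' CpG are assumed unmethylated and always convert.
#'
#' @param sequence DNA string over `A`,`C`,`G`,`T` (case-insensitive,
#'   whitespace ignored).
#' @param methylation Logical: either a single flag applied to every CpG
#'   site, or one value per CpG site (5' to 3').
#' @return The converted DNA string, same length.
#' @examples
#' bisulfite_convert("ACGT", methylation = FALSE)
#' bisulfite_convert("ACGT", methylation = TRUE)
#' @export
bisulfite_convert <- function(sequence, methylation = FALSE) {
  s <- amplicon_sequence(sequence)
  if (grepl("[^ACGT]", s)) abort("Sequence must contain only A, C, G, T.")
  sites <- find_cpg_sites(s)
  k <- length(sites)
  meth <- expand_methylation(methylation, k)
  chars <- strsplit(s, "")[[1]]
  is_c <- chars == "C"
  protected <- rep(FALSE, length(chars))
  protected[sites[meth]] <- TRUE
  chars[is_c & !protected] <- "T"
  paste(chars, collapse = "")
}

expand_methylation <- function(methylation, n_sites) {
  if (!is.logical(methylation) || anyNA(methylation))
    abort("`methylation` must be logical with no NA.")
  if (length(methylation) == 1) return(rep(methylation, n_sites))
  if (length(methylation) != n_sites)
    abort(sprintf(
      "`methylation` has length %d but the sequence has %d CpG sites.",
      length(methylation), n_sites))
  methylation
}

#' Reverse-strand in-vitro transcription
#'
#' The T7 tag on the reverse primer drives transcription of the PCR product
#' from the reverse strand, so the transcript is the reverse complement of
#' the forward sequence in the RNA alphabet, read 5' to 3'.
#'
#' @param bisulfite_seq DNA string over `A`,`C`,`G`,`T`.
#' @return Transcript string over `A`,`C`,`G`,`U`.
#' @examples
#' transcribe_reverse("GGGATGTTTTAGG")
#' @export
transcribe_reverse <- function(bisulfite_seq) {
  s <- amplicon_sequence(bisulfite_seq)
  if (grepl("[^ACGT]", s)) abort("Sequence must contain only A, C, G, T.")
  paste(rev(strsplit(chartr("ACGT", "UGCA", s), "")[[1]]), collapse = "")
}

#' Uracil-specific cleavage of a transcript
#'
#' RNase A cuts the T-reaction transcript 3' of every uridine (the
#' transcript incorporates deoxy-C, so C positions are resistant), so the
#' transcript splits immediately after each U. Fragments come back 5' to 3';
#' a trailing fragment without a U may exist; empty fragments never occur.
#'
#' @param transcript Non-empty string over `A`,`C`,`G`,`U`.
#' @return Character vector of fragment sequences whose concatenation is the
#'   transcript.
#' @examples
#' t_cleave("CCUAAAACAUCCC")
#' @export
t_cleave <- function(transcript) {
  stopifnot(is.character(transcript), length(transcript) == 1)
  if (nchar(transcript) == 0) abort("Transcript must be non-empty.")
  if (grepl("[^ACGU]", transcript))
    abort("Transcript must contain only A, C, G, U.")
  frags <- regmatches(transcript,
                      gregexpr("[ACG]*U|[ACG]+$", transcript))[[1]]
  frags
}

#' Full in-silico fragmentation of an amplicon
#'
#' Composes [bisulfite_convert()], [transcribe_reverse()] and [t_cleave()]
#' and annotates every fragment with its coordinates, base composition, the
#' CpG sites it carries, the number of converted non-CpG cytosines it
#' witnesses, and its mass. A CpG site belongs to the fragment containing
#' the transcript base templated by its G; because the two transcript bases
#' arising from a CpG are adjacent and neither is ever a U, the pair always
#' sits in one fragment and methylation state never moves a cleavage site.
#'
#' `base_mass` is the fully-unmethylated mass of the fragment; `mass` is the
#' mass at the methylation state actually simulated (`base_mass` +
#' 16 Da per methylated CpG).
#'
#' @param amplicon An `annotated_amplicon`, or a DNA string.
#' @param methylation Per-CpG-site logical, or one flag for all sites.
#' @param model A [mass_model()].
#' @return A tibble of class `cleave_fragments`, one row per fragment in
#'   transcript 5'-to-3' order, with columns `fragment`, `transcript_seq`,
#'   `tr_start`, `tr_end`, `fwd_start`, `fwd_end`, `length`, `n_A`, `n_C`,
#'   `n_G`, `n_U`, `cpg_sites` (list), `n_cpg`, `n_methylated`,
#'   `converted_c`, `base_mass`, `mass`.
#' @examples
#' amp <- parse_annotated_sequence("ACTTGGGACGCCTCAGG", "toy")
#' fragment_amplicon(amp)
#' @export
fragment_amplicon <- function(amplicon, methylation = FALSE,
                              model = mass_model()) {
  if (!inherits(amplicon, "annotated_amplicon"))
    amplicon <- parse_annotated_sequence(amplicon_sequence(amplicon))
  s <- amplicon$sequence
  len <- nchar(s)
  sites <- amplicon$cpg_sites
  meth <- expand_methylation(methylation, length(sites))

  bs <- bisulfite_convert(s, meth)
  transcript <- transcribe_reverse(bs)
  seqs <- t_cleave(transcript)
  lens <- nchar(seqs)
  tr_end <- cumsum(lens)
  tr_start <- tr_end - lens + 1L

  # transcript index templated by the G of CpG site p (G at p+1): len - p
  site_tr_idx <- len - sites
  # transcript indices of converted non-CpG cytosines (forward C -> A)
  all_c <- as.integer(gregexpr("C", s)[[1]])
  all_c <- all_c[all_c > 0]
  nonCpG_c <- setdiff(all_c, sites)
  conv_tr_idx <- len - nonCpG_c + 1L

  comp <- t(vapply(seqs, base_composition, integer(4), USE.NAMES = FALSE))
  colnames(comp) <- c("A", "C", "G", "U")
  frag_of <- function(idx) findInterval(idx, tr_start)
  site_frag <- frag_of(site_tr_idx)
  conv_frag <- frag_of(conv_tr_idx)

  cpg_list <- lapply(seq_along(seqs), function(i)
    which(site_frag == i))
  n_meth <- vapply(cpg_list, function(k) sum(meth[k]), integer(1))
  mass <- vapply(seq_along(seqs), function(i)
    fragment_mass(comp[i, ], 0, model), numeric(1))

  out <- tibble(
    fragment = seq_along(seqs),
    transcript_seq = seqs,
    tr_start = tr_start, tr_end = tr_end,
    fwd_start = len - tr_end + 1L, fwd_end = len - tr_start + 1L,
    length = lens,
    n_A = comp[, 1], n_C = comp[, 2], n_G = comp[, 3], n_U = comp[, 4],
    cpg_sites = cpg_list,
    n_cpg = lengths(cpg_list),
    n_methylated = n_meth,
    converted_c = as.integer(tabulate(conv_frag, nbins = length(seqs))),
    base_mass = round(mass - n_meth * model$methylation_shift, 3),
    mass = mass)
  structure(out,
            class = c("cleave_fragments", class(out)),
            amplicon = amplicon$name, model = model, methylation = meth)
}
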