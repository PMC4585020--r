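#' Parse an annotated amplicon sequence
#'
#' Amplicon sequences are exchanged as plain text with a light markup:
#' `[...]` encloses the target region of interest (at most one span),
#' `<X>` masks positions carrying a common SNP or repeat, a bare `>` marks
#' the end of the forward primer and a bare `<` (with no closing `>` before
#' the end of the string) marks the start of the reverse primer. Whitespace
#' and line breaks are ignored; lower-case bases (primer tags) are accepted
#' and upper-cased.
#'
#' Disambiguation between SNP masks and primer markers is positional: a `<`
#' opens a mask only if a `>` follows it with no intervening `<`; a `>` seen
#' while no mask is open is the forward-primer marker; a trailing unclosed
#' `<` is the reverse-primer marker. Nested markup is rejected rather than
#' guessed at.
#'
#' All coordinates are 1-based inclusive on the stripped sequence. CpG sites
#' are the positions of the C of every CG dinucleotide, numbered from the 5'
#' end; a site whose C or G falls in a masked span is flagged
#' (`cpg_masked`), never dropped — exclusion is a QC-stage decision.
#'
#' @param text Markup string (DNA letters, whitespace, `[ ] < >`).
#' @param name Identifier for the amplicon.
#' @return An object of class `annotated_amplicon`: a list with fields
#'   `name`, `sequence`, `target_start`, `target_end`, `masked_positions`,
#'   `forward_primer_end`, `reverse_primer_start`, `cpg_sites`,
#'   `cpg_masked`.
#' @examples
#' amp <- parse_annotated_sequence(
#'   "AATGGAGTA<T>AGAAATAAGG[GCGAGCTACGCGA]TTTGCTCATGG", "example")
#' amp$masked_positions
#' count_cpg_sites(amp)
#' @export
parse_annotated_sequence <- function(text, name = "amplicon") {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(gsub("\\s", "", text), "", fixed = FALSE)[[1]]
  if (length(chars) == 0) abort("Empty sequence.")

  seq_chars <- character(0)
  masked <- integer(0)
  target_start <- NA_integer_; target_end <- NA_integer_
  fwd_end <- NA_integer_; rev_start <- NA_integer_
  in_mask <- FALSE
  in_target <- FALSE
  seen_target <- FALSE

  i <- 1L
  nchars <- length(chars)
  while (i <= nchars) {
    ch <- chars[[i]]
    if (ch == "[") {
      if (in_mask) abort(sprintf("'[' inside a <...> mask at offset %d.", i))
      if (in_target) abort(sprintf("Nested '[' at offset %d.", i))
      if (seen_target) abort(sprintf(
        "Multiple [...] target spans (second '[' at offset %d).", i))
      in_target <- TRUE; seen_target <- TRUE
      target_start <- length(seq_chars) + 1L
    } else if (ch == "]") {
      if (!in_target) abort(sprintf("Unbalanced ']' at offset %d.", i))
      in_target <- FALSE
      target_end <- length(seq_chars)
      if (target_end < target_start)
        abort(sprintf("Empty [] target span ending at offset %d.", i))
    } else if (ch == "<") {
      if (in_mask)
        abort(sprintf("Nested '<' at offset %d; nesting is rejected.", i))
      # mask iff a '>' follows with no intervening '<'
      rest <- if (i < nchars) chars[(i + 1L):nchars] else character(0)
      nxt_close <- match(">", rest)
      nxt_open <- match("<", rest)
      is_mask <- !is.na(nxt_close) &&
        (is.na(nxt_open) || nxt_close < nxt_open)
      if (is_mask) {
        in_mask <- TRUE
        mask_from <- length(seq_chars) + 1L
      } else {
        if (!is.na(rev_start))
          abort(sprintf("Second reverse-primer marker '<' at offset %d.", i))
        rev_start <- length(seq_chars) + 1L
      }
    } else if (ch == ">") {
      if (in_mask) {
        in_mask <- FALSE
        if (length(seq_chars) < mask_from)
          abort(sprintf("Empty <> mask span ending at offset %d.", i))
        masked <- c(masked, mask_from:length(seq_chars))
      } else {
        if (!is.na(fwd_end))
          abort(sprintf("Second forward-primer marker '>' at offset %d.", i))
        fwd_end <- length(seq_chars)
        if (fwd_end == 0L)
          abort("Forward-primer marker '>' before any sequence.")
      }
    } else {
      up <- toupper(ch)
      if (!up %in% c("A", "C", "G", "T"))
        abort(sprintf("Non-DNA character '%s' at offset %d.", ch, i))
      seq_chars <- c(seq_chars, up)
    }
    i <- i + 1L
  }
  if (in_mask) abort("Unbalanced '<': mask span never closed.")
  if (in_target) abort("Unbalanced '[': target span never closed.")
  if (!is.na(fwd_end) && !is.na(rev_start) && fwd_end >= rev_start)
    abort("Forward-primer end must precede reverse-primer start.")
  if (!is.na(rev_start) && rev_start > length(seq_chars))
    abort("Reverse-primer marker '<' after the last base.")

  sequence <- paste(seq_chars, collapse = "")
  len <- length(seq_chars)
  if (!seen_target) { target_start <- 1L; target_end <- len }
  cpg <- find_cpg_sites(sequence)
  new_annotated_amplicon(
    name = name, sequence = sequence,
    target_start = target_start, target_end = target_end,
    masked_positions = sort(unique(masked)),
    forward_primer_end = fwd_end, reverse_primer_start = rev_start,
    cpg_sites = cpg)
}

new_annotated_amplicon <- function(name, sequence, target_start, target_end,
                                   masked_positions, forward_primer_end,
                                   reverse_primer_start, cpg_sites) {
  cpg_masked <- cpg_sites %in% masked_positions |
    (cpg_sites + 1L) %in% masked_positions
  amp <- structure(
    list(name = name, sequence = sequence,
         target_start = as.integer(target_start),
         target_end = as.integer(target_end),
         masked_positions = as.integer(masked_positions),
         forward_primer_end = as.integer(forward_primer_end),
         reverse_primer_start = as.integer(reverse_primer_start),
         cpg_sites = as.integer(cpg_sites),
         cpg_masked = cpg_masked),
    class = "annotated_amplicon")
  validate_amplicon(amp)
}

validate_amplicon <- function(amp) {
  len <- nchar(amp$sequence)
  s <- amp$sequence
  if (grepl("[^ACGT]", s)) abort("Sequence contains non-DNA residues.")
  for (p in amp$cpg_sites) {
    if (substr(s, p, p + 1L) != "CG")
      abort(sprintf("cpg_sites invariant violated at position %d.", p))
  }
  if (is.unsorted(amp$cpg_sites, strictly = TRUE) && length(amp$cpg_sites) > 1)
    abort("cpg_sites must be strictly increasing.")
  if (any(amp$masked_positions < 1L | amp$masked_positions > len))
    abort("masked_positions outside the sequence.")
  if (amp$target_start < 1L || amp$target_end > len ||
      amp$target_start > amp$target_end)
    abort("target interval outside the sequence.")
  amp
}

#' Sequence of an amplicon
#' @param amplicon An `annotated_amplicon` (or a plain DNA string).
#' @return Upper-case DNA string.
#' @export
amplicon_sequence <- function(amplicon) {
  if (inherits(amplicon, "annotated_amplicon")) amplicon$sequence
  else toupper(gsub("\\s", "", amplicon))
}

find_cpg_sites <- function(sequence) {
  m <- gregexpr("(?=CG)", sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Count CpG sites in an amplicon
#' @inheritParams amplicon_sequence
#' @return Number of CG dinucleotides (they cannot self-overlap).
#' @examples
#' count_cpg_sites("CGCGCG")
#' @export
count_cpg_sites <- function(amplicon) {
  if (inherits(amplicon, "annotated_amplicon"))
    length(amplicon$cpg_sites)
  else length(find_cpg_sites(amplicon_sequence(amplicon)))
}

#' Render an amplicon back to markup text
#'
#' Inverse of [parse_annotated_sequence()]: re-parsing the rendered string
#' yields an identical amplicon.
#' @param amplicon An `annotated_amplicon`.
#' @return Markup string.
#' @export
render_annotated_sequence <- function(amplicon) {
  stopifnot(inherits(amplicon, "annotated_amplicon"))
  chars <- strsplit(amplicon$sequence, "")[[1]]
  len <- length(chars)
  pre <- character(len)   # markup emitted before base i
  post <- character(len)  # markup emitted after base i
  whole_target <- amplicon$target_start == 1L && amplicon$target_end == len
  if (!whole_target) {
    pre[amplicon$target_start] <- paste0(pre[amplicon$target_start], "[")
    post[amplicon$target_end] <- paste0("]", post[amplicon$target_end])
  }
  if (length(amplicon$masked_positions) > 0) {
    runs <- split(amplicon$masked_positions,
                  cumsum(c(1L, diff(amplicon$masked_positions) != 1L)))
    for (r in runs) {
      pre[r[1]] <- paste0(pre[r[1]], "<")
      post[r[length(r)]] <- paste0(">", post[r[length(r)]])
    }
  }
  if (!is.na(amplicon$forward_primer_end))
    post[amplicon$forward_primer_end] <-
      paste0(post[amplicon$forward_primer_end], ">")
  if (!is.na(amplicon$reverse_primer_start))
    pre[amplicon$reverse_primer_start] <-
      paste0("<", pre[amplicon$reverse_primer_start])
  paste0(paste0(pre, chars, post), collapse = "")
}

#' Read amplicons from a FASTA file
#'
#' Unannotated sequences: the whole sequence is the target, no masks or
#' primer marks.
#' @param path FASTA file (single or multi-record).
#' @return A list of `annotated_amplicon`, named by record.
#' @export
read_amplicon_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    parse_annotated_sequence(as.character(set[[i]]),
                             name = sub("\\s.*$", "", names(set)[i]))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Read an amplicon from annotated plain text
#'
#' Reads a whole text file (any line wrapping), strips whitespace and parses
#' the markup.
#' @param path Text file containing one (possibly wrapped) annotated
#'   sequence.
#' @param name Amplicon name; defaults to the file stem.
#' @export
read_amplicon_text <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_annotated_sequence(txt, name = name)
}

#' @export
print.annotated_amplicon <- function(x, ...) {
  cat(sprintf("<annotated_amplicon> %s (%d bp)\n", x$name, nchar(x$sequence)))
  cat(sprintf("  target: [%d, %d]   masked positions: %d\n",
              x$target_start, x$target_end, length(x$masked_positions)))
  if (!is.na(x$forward_primer_end) || !is.na(x$reverse_primer_start))
    cat(sprintf("  primers: forward ends %s, reverse starts %s\n",
                x$forward_primer_end, x$reverse_primer_start))
  cat(sprintf("  CpG sites (%d): %s\n", length(x$cpg_sites),
              paste(x$cpg_sites, collapse = ", ")))
  invisible(x)
}

#' @describeIn parse_annotated_sequence Tidy view: one row per CpG site with
#'   its position, number and mask flag.
#' @param x An `annotated_amplicon`.
#' @param ... Unused.
#' @export
tidy.annotated_amplicon <- function(x, ...) {
  tibble(
    amplicon = x$name,
    site = seq_along(x$cpg_sites),
    position = x$cpg_sites,
    in_target = x$cpg_sites >= x$target_start &
      x$cpg_sites <= x$target_end,
    masked = x$cpg_masked)
}
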