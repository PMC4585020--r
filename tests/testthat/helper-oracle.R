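# Brute-force fragmentation oracle: plain character loops, no shared code
# with the package implementation.

oracle_fragments <- function(seq) {
  ch <- unlist(strsplit(seq, ""))
  n <- length(ch)
  for (i in seq_len(n)) if (ch[i] == "C") ch[i] <- "T"  # all-unmethylated
  rna <- character(n)
  for (i in seq_len(n)) {
    b <- ch[n - i + 1]
    rna[i] <- switch(b, A = "U", T = "A", G = "C", C = "G")
  }
  frs <- character(0); cur <- ""
  for (i in seq_len(n)) {
    cur <- paste0(cur, rna[i])
    if (rna[i] == "U") { frs <- c(frs, cur); cur <- "" }
  }
  if (nchar(cur) > 0) frs <- c(frs, cur)
  frs
}

oracle_mass <- function(fragment, model = mass_model()) {
  ch <- unlist(strsplit(fragment, ""))
  total <- model$kappa
  for (b in ch) total <- total + model$residue_mass[[b]]
  round(total, 3)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

lep_amplicon <- function() {
  read_amplicon_text(
    system.file("extdata", "lep_amplicon.txt", package = "epicleave"),
    name = "LEP")
}

# Published triplicate standard deviations for the silent-overlap unit of
# the leptin worked example (10 biological samples).
published_cpg3_sd <- c(0.103, 0.076, 0.119, 0.248, 0.025, 0.319,
                       0.154, 0.112, 0.020, 0.140)

# Build an export grid (as text lines) whose triplicates have exactly the
# requested per-sample SD on the focal unit: deviations (-s, 0, +s) around a
# common mean have sample SD exactly s.
worked_example_grid <- function(cpg3_sd = published_cpg3_sd, mean = 0.5) {
  units <- c("CpG_1", "CpG_2", "CpG_3", "CpG_4")
  lines <- c(paste(c("Sample", units), collapse = "\t"),
             paste(c("Warning", "L_mass", "NA", "SN3", "NA"),
                   collapse = "\t"))
  well <- 0
  for (s in seq_along(cpg3_sd)) {
    dev <- c(-cpg3_sd[s], 0, cpg3_sd[s])
    for (r in 1:3) {
      well <- well + 1
      vals <- c("NA",
                sprintf("%.4f", 0.8 + c(-0.02, 0, 0.02)[r]),
                sprintf("%.4f", mean + dev[r]),
                sprintf("%.4f", 0.9 + c(-0.01, 0, 0.01)[r]))
      lines <- c(lines, paste(c(sprintf("%03d_%d_%02d", well, s, r), vals),
                              collapse = "\t"))
    }
  }
  for (ctrl in c("gDNA", "water"))
    lines <- c(lines, paste(c(ctrl, "NA", "NA", "NA", "NA"),
                            collapse = "\t"))
  lines
}
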