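# Shared fixture builders. Everything is generated in code; no binary
# or stored fixtures.

# A tiny named reference from literal strings.
tiny_ref <- function(...) {
  seqs <- c(...)
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(seqs)
  out
}

# Write a VCF file from raw lines (for parser-facing tests).
write_vcf_lines <- function(body, samples = NULL, dir = tempdir()) {
  path <- tempfile("fix", tmpdir = dir, fileext = ".vcf")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  writeLines(c("##fileformat=VCFv4.2",
               paste(cols, collapse = "\t"), body), path)
  path
}

# Minimal line metadata for n samples named line01..lineNN.
tiny_meta <- function(n, family = rep("", n)) {
  data.frame(sample = sprintf("line%02d", seq_len(n)),
             dosage_gy = rep(16, n),
             selfing_generations = rep(5L, n),
             family = family, stringsAsFactors = FALSE)
}

# A multi-sample VariantSet built from a compact spec: one row per
# variant, genotypes given as alt dosages.
tiny_vs <- function(chrom, pos, ref, alt, gt, qual = NULL, dp = NULL) {
  chrom <- rep_len(chrom, length(pos))
  gt <- matrix(gt, nrow = length(pos), byrow = TRUE)
  n <- ncol(gt)
  if (is.null(qual)) qual <- rep(100, length(pos))
  if (is.null(dp)) dp <- matrix(30L, length(pos), n)
  variant_set(chrom, pos, ref, alt, qual, gt = gt, dp = dp,
              samples = sprintf("line%02d", seq_len(n)))
}

# Cache one small simulated study per session to keep the suite fast.
small_study_cache <- new.env(parent = emptyenv())
get_small_study <- function() {
  if (is.null(small_study_cache$st)) {
    cfg <- sim_config(seed = 11, contigs = c(chr1 = 3e5, chr2 = 3e5))
    small_study_cache$st <- simulate_study(cfg, n_genes = 4)
  }
  small_study_cache$st
}
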