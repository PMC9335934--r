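#' Construct a VariantSet
#'
#' A \code{VariantSet} holds normalized, biallelic variant records plus
#' per-sample genotype information. Genotypes are stored as an integer
#' matrix of alternate-allele dosages (0 = hom ref, 1 = het, 2 = hom
#' alt, \code{NA} = missing), one row per variant and one column per
#' sample; read depths are an optional parallel matrix.
#'
#' @param chrom character vector of contig names.
#' @param pos integer vector of 1-based positions of the first
#'   reference base.
#' @param ref,alt character vectors of reference/alternate alleles
#'   (\code{[ACGT]+}, \code{ref != alt}).
#' @param qual numeric vector of quality scores (\code{NA} allowed).
#' @param gt integer matrix of alt dosages (variants x samples), or
#'   \code{NULL} for site-only sets.
#' @param dp integer matrix of depths matching \code{gt}, or \code{NULL}.
#' @param samples character vector of sample names (columns of
#'   \code{gt}).
#'
#' @return An object of class \code{VariantSet}.
#' @export
variant_set <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        qual = rep(NA_real_, length(chrom)),
                        gt = NULL, dp = NULL, samples = NULL) {
  n <- length(chrom)
  fail_if(length(pos) != n || length(ref) != n || length(alt) != n,
          "chrom/pos/ref/alt must have equal length")
  if (length(qual) == 0L && n == 0L) qual <- numeric(0)
  fail_if(length(qual) != n, "qual must match the number of variants")
  if (n > 0) {
    ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
    fail_if(!all(ok), "alleles must match [ACGT]+ (offending record %d)",
            which(!ok)[1])
    fail_if(any(ref == alt), "ref and alt must differ")
    fail_if(any(pos < 1), "pos must be >= 1")
  }
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    storage.mode(gt) <- "integer"
    fail_if(nrow(gt) != n, "gt must have one row per variant")
    if (is.null(samples)) samples <- colnames(gt)
    if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
    colnames(gt) <- samples
    if (!is.null(dp)) {
      dp <- as.matrix(dp)
      storage.mode(dp) <- "integer"
      fail_if(!all(dim(dp) == dim(gt)), "dp must match gt dimensions")
      colnames(dp) <- samples
    }
  } else {
    samples <- samples %||% character(0)
  }
  structure(list(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = as.numeric(qual),
    gt = gt, dp = dp,
    samples = samples
  ), class = "VariantSet")
}

#' @export
length.VariantSet <- function(x) length(x$pos)

#' Number of variants in a VariantSet
#' @param x a \code{VariantSet}.
#' @return integer count of records.
#' @export
n_variants <- function(x) length(x$pos)

#' @export
`[.VariantSet` <- function(x, i, ...) {
  variant_set(x$chrom[i], x$pos[i], x$ref[i], x$alt[i], x$qual[i],
              gt = if (!is.null(x$gt)) x$gt[i, , drop = FALSE],
              dp = if (!is.null(x$dp)) x$dp[i, , drop = FALSE],
              samples = x$samples)
}

#' @export
print.VariantSet <- function(x, ...) {
  cat(sprintf("VariantSet: %d variants, %d samples\n",
              length(x), length(x$samples)))
  if (length(x) > 0) {
    cls <- classify_variant(x$ref, x$alt)
    tb <- table(cls$label)
    cat("  classes:", paste(names(tb), tb, sep = "=", collapse = ", "),
        "\n")
    show <- head(as_variant_frame(x), 6)
    print(show, row.names = FALSE)
    if (length(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Variant records as a data frame
#'
#' @param x a \code{VariantSet}.
#' @return data frame with columns \code{chrom, pos, ref, alt, qual}.
#' @export
as_variant_frame <- function(x) {
  data.frame(chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
             qual = x$qual, stringsAsFactors = FALSE)
}

#' Canonical variant key
#'
#' \code{chrom:pos:ref:alt} after normalization; identical events
#' compare equal under this key.
#' @param x a \code{VariantSet}.
#' @return character vector of keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Classify variants as SNP / insertion / deletion / other
#'
#' The signed length is \code{nchar(alt) - nchar(ref)}: zero for SNPs
#' (and for equal-length multi-nucleotide substitutions, which are
#' labelled \code{other}), positive for insertions, negative for
#' deletions.
#'
#' @param ref,alt character vectors of normalized alleles.
#' @return data frame with columns \code{label} (one of \code{"SNP"},
#'   \code{"insertion"}, \code{"deletion"}, \code{"other"}) and
#'   \code{signed_length}.
#' @export
classify_variant <- function(ref, alt) {
  fail_if(any(nchar(ref) == 0 | nchar(alt) == 0),
          "empty allele string")
  sl <- nchar(alt) - nchar(ref)
  label <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP",
           ifelse(sl > 0, "insertion",
           ifelse(sl < 0, "deletion", "other")))
  # equal-length block substitutions carry no indel length
  sl[label %in% c("SNP", "other")] <- 0L
  data.frame(label = label, signed_length = as.integer(sl),
             stringsAsFactors = FALSE)
}

#' Nonreference allele count of each variant
#'
#' Counts alternate-allele copies across all called genotypes; missing
#' genotypes contribute zero.
#'
#' @param x a \code{VariantSet} with genotypes.
#' @return integer vector, one count per variant.
#' @export
nonref_allele_count <- function(x) {
  fail_if(is.null(x$gt), "VariantSet has no genotypes")
  as.integer(rowSums(x$gt, na.rm = TRUE))
}

## --- normalization -------------------------------------------------

# Left-align and trim one allele pair against the reference.
# Standard parsimony/left-shift: drop shared trailing bases (extending
# left from the reference when an allele would empty), then drop shared
# leading bases. Returns list(pos, ref, alt).
normalize_one <- function(pos, ref, alt, contig_seq) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0 && na > 0 &&
        substr(ref, nr, nr) == substr(alt, na, na) &&
        (nr > 1 || na > 1)) {
      ref <- substr(ref, 1, nr - 1)
      alt <- substr(alt, 1, na - 1)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        fail_if(pos <= 1, "cannot left-align past the start of a contig")
        pos <- pos - 1
        b <- substr(contig_seq, pos, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else break
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variants against a reference
#'
#' Applies left-alignment and parsimony trimming so that identical
#' events compare equal, a prerequisite for subtracting panel variants
#' from treatment variants. SNPs are returned unchanged.
#'
#' @param x a \code{VariantSet}.
#' @param reference a \code{\link[Biostrings]{DNAStringSet}} of contigs.
#' @return a normalized \code{VariantSet}.
#' @export
normalize_variants <- function(x, reference) {
  if (length(x) == 0) return(x)
  seqs <- as.character(reference)
  need <- nchar(x$ref) > 1 | nchar(x$alt) > 1
  for (i in which(need)) {
    cs <- seqs[[x$chrom[i]]]
    nz <- normalize_one(x$pos[i], x$ref[i], x$alt[i], cs)
    x$pos[i] <- nz$pos; x$ref[i] <- nz$ref; x$alt[i] <- nz$alt
  }
  x
}

#' Verify REF alleles against the reference sequence
#'
#' A mismatch is fatal: it signals the wrong reference build.
#'
#' @param x a \code{VariantSet}.
#' @param reference a \code{\link[Biostrings]{DNAStringSet}}.
#' @return \code{x}, invisibly, if all REF alleles match.
#' @export
check_ref_alleles <- function(x, reference) {
  if (length(x) == 0) return(invisible(x))
  fail_if(!all(x$chrom %in% names(reference)),
          "contig '%s' absent from reference",
          setdiff(x$chrom, names(reference))[1])
  lens <- Biostrings::width(reference)[match(x$chrom, names(reference))]
  over <- x$pos + nchar(x$ref) - 1 > lens
  fail_if(any(over), "variant at %s:%d extends past the contig end",
          x$chrom[which(over)[1]], x$pos[which(over)[1]])
  seqs <- as.character(reference)
  obs <- vapply(seq_len(length(x)), function(i) {
    substr(seqs[[x$chrom[i]]], x$pos[i], x$pos[i] + nchar(x$ref[i]) - 1)
  }, character(1))
  bad <- obs != x$ref
  fail_if(any(bad),
          paste0("REF allele mismatch with reference at %s:%d ",
                 "(VCF %s, FASTA %s); wrong reference build?"),
          x$chrom[which(bad)[1]], x$pos[which(bad)[1]],
          x$ref[which(bad)[1]], obs[which(bad)[1]])
  invisible(x)
}

#' Combine VariantSets over the same samples
#' @param ... \code{VariantSet} objects with identical sample panels.
#' @return a single concatenated \code{VariantSet}.
#' @export
bind_variants <- function(...) {
  xs <- list(...)
  xs <- xs[vapply(xs, length, 1L) > 0]
  if (length(xs) == 0) return(variant_set())
  samp <- xs[[1]]$samples
  for (x in xs) fail_if(!identical(x$samples, samp),
                        "sample panels differ across VariantSets")
  has_gt <- !is.null(xs[[1]]$gt)
  variant_set(
    unlist(lapply(xs, `[[`, "chrom")),
    unlist(lapply(xs, `[[`, "pos")),
    unlist(lapply(xs, `[[`, "ref")),
    unlist(lapply(xs, `[[`, "alt")),
    unlist(lapply(xs, `[[`, "qual")),
    gt = if (has_gt) do.call(rbind, lapply(xs, `[[`, "gt")),
    dp = if (has_gt && !is.null(xs[[1]]$dp))
      do.call(rbind, lapply(xs, `[[`, "dp")),
    samples = samp)
}

#' Sort a VariantSet by genomic position
#' @param x a \code{VariantSet}.
#' @return \code{x} ordered by (chrom, pos, ref, alt).
#' @export
sort_variants <- function(x) {
  x[order(x$chrom, x$pos, x$ref, x$alt)]
}
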