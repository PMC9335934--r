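# Readers and writers for the formats the pipeline touches. VCF parsing
# is delegated to vcfR; FASTA to Biostrings; BED to rtracklayer.
# Coordinate conventions meet only here: variants are VCF 1-based
# inclusive internally, masks are BED 0-based half-open on disk and
# 1-based GRanges in memory.

#' Read variants from a VCF file
#'
#' Parses a VCF 4.x file (plain or bgzipped), splits multiallelic
#' records into biallelic variants (each split record inherits the
#' original QUAL), excludes symbolic/structural alleles and spanning
#' deletions, left-align-normalizes indels when a reference is given,
#' and verifies REF alleles against the reference sequence.
#'
#' @param path path to the VCF file.
#' @param reference optional \code{\link[Biostrings]{DNAStringSet}};
#'   when supplied, REF alleles are checked (a mismatch is fatal) and
#'   indels are normalized.
#' @param verbose emit a message with the number of excluded
#'   symbolic-allele records.
#' @return a \code{\link{variant_set}} with attribute
#'   \code{"n_symbolic_excluded"}.
#' @export
read_variants <- function(path, reference = NULL, verbose = FALSE) {
  fail_if(!file.exists(path), "no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    out <- variant_set()
    attr(out, "n_symbolic_excluded") <- 0L
    return(out)
  }
  gt_raw <- NULL; dp_raw <- NULL; samples <- character(0)
  if (ncol(v@gt) > 1) {
    gt_raw <- vcfR::extract.gt(v, element = "GT")
    samples <- colnames(gt_raw)
    fmt <- strsplit(v@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
    if ("DP" %in% fmt)
      dp_raw <- suppressWarnings(
        vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  }

  chrom <- character(0); pos <- integer(0); ref <- character(0)
  alt <- character(0); qual <- numeric(0)
  gt_rows <- list(); dp_rows <- list()
  n_symbolic <- 0L

  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    r <- fix[i, "REF"]
    q <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    gti <- if (!is.null(gt_raw)) gt_raw[i, ] else NULL
    alleles <- if (!is.null(gti)) {
      lapply(strsplit(ifelse(is.na(gti), ".", gti), "[/|]"),
             function(a) suppressWarnings(as.integer(a)))
    }
    for (k in seq_along(alts)) {
      a <- alts[k]
      if (!grepl("^[ACGTacgt]+$", a) || !grepl("^[ACGTacgt]+$", r)) {
        n_symbolic <- n_symbolic + 1L
        next
      }
      chrom <- c(chrom, fix[i, "CHROM"])
      pos <- c(pos, as.integer(fix[i, "POS"]))
      ref <- c(ref, toupper(r))
      alt <- c(alt, toupper(a))
      qual <- c(qual, q)
      if (!is.null(gti)) {
        dos <- vapply(alleles, function(al) {
          if (all(is.na(al))) return(NA_integer_)
          sum(al == k, na.rm = TRUE)
        }, integer(1))
        gt_rows[[length(gt_rows) + 1L]] <- dos
        dp_rows[[length(dp_rows) + 1L]] <-
          if (!is.null(dp_raw)) as.integer(dp_raw[i, ])
          else rep(NA_integer_, length(samples))
      }
    }
  }
  gt <- if (length(gt_rows)) do.call(rbind, gt_rows)
  dp <- if (length(dp_rows)) do.call(rbind, dp_rows)
  out <- variant_set(chrom, pos, ref, alt, qual, gt = gt, dp = dp,
                     samples = samples)
  if (!is.null(reference)) {
    check_ref_alleles(out, reference)
    out <- normalize_variants(out, reference)
  }
  if (verbose && n_symbolic > 0)
    message(sprintf("excluded %d symbolic/structural allele record(s)",
                    n_symbolic))
  attr(out, "n_symbolic_excluded") <- n_symbolic
  out
}

#' Write a VariantSet as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 file with GT (and DP when available)
#' genotype fields, suitable for round-tripping through
#' \code{\link{read_variants}}. Output is deterministic byte-for-byte
#' for a given input.
#'
#' @param x a \code{\link{variant_set}}.
#' @param path output file path.
#' @param reference optional \code{DNAStringSet} used to emit contig
#'   header lines.
#' @param info optional character vector (one per variant) of
#'   preformatted INFO fields, e.g. \code{"CARRIER=line7;CLASS=SNP"}.
#' @param info_header optional character vector of extra \code{##INFO}
#'   header lines.
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(x, path, reference = NULL, info = NULL,
                      info_header = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=fnmut")
  if (!is.null(reference))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference), Biostrings::width(reference)))
  hdr <- c(hdr,
    '##INFO=<ID=.,Number=0,Type=Flag,Description="placeholder">'[0],
    info_header,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO")
  has_gt <- !is.null(x$gt) && length(x$samples) > 0
  if (has_gt) cols <- c(cols, "FORMAT", x$samples)
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (length(x) > 0) {
    qual <- ifelse(is.na(x$qual), ".",
                   formatC(x$qual, format = "g", digits = 6))
    inf <- if (is.null(info)) rep(".", length(x)) else info
    body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, qual, "PASS",
                  inf, sep = "\t")
    if (has_gt) {
      gstr <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L],
                     nrow = nrow(x$gt))
      gstr[is.na(x$gt)] <- "./."
      if (!is.null(x$dp)) {
        dstr <- ifelse(is.na(x$dp), ".", as.character(x$dp))
        gstr <- matrix(paste(gstr, dstr, sep = ":"), nrow = nrow(gstr))
        fmt <- "GT:DP"
      } else fmt <- "GT"
      body <- paste(body, fmt,
                    apply(gstr, 1, paste, collapse = "\t"), sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference genome FASTA
#' @param path FASTA file path.
#' @return a \code{\link[Biostrings]{DNAStringSet}}.
#' @export
read_reference <- function(path) {
  fail_if(!file.exists(path), "no such file: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  # keep only the first word of each header, as aligners do
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a reference genome FASTA
#' @param reference a \code{DNAStringSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path, width = 70L)
  invisible(path)
}

#' Read mask intervals from a BED3 file
#'
#' BED is 0-based half-open on disk; in memory masks are a merged,
#' sorted \code{\link[GenomicRanges]{GRanges}} (1-based inclusive).
#'
#' @param path BED file path.
#' @return a reduced \code{GRanges}.
#' @export
read_mask_bed <- function(path) {
  fail_if(!file.exists(path), "no such file: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Write mask intervals to BED3
#' @param masks a \code{GRanges} of mask intervals.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mask_bed <- function(masks, path) {
  masks <- GenomicRanges::reduce(GenomicRanges::sort(masks))
  df <- data.frame(as.character(GenomicRanges::seqnames(masks)),
                   GenomicRanges::start(masks) - 1L,
                   GenomicRanges::end(masks))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-line metadata
#'
#' Tab-separated with header
#' \code{sample dosage_gy selfing_generations family}; \code{family}
#' marks sibling groups and may be empty.
#'
#' @param path TSV path.
#' @return data frame of line metadata.
#' @export
read_line_meta <- function(path) {
  fail_if(!file.exists(path), "no such file: %s", path)
  m <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE,
                  colClasses = c("character", "numeric", "integer",
                                 "character"))
  need <- c("sample", "dosage_gy", "selfing_generations", "family")
  fail_if(!all(need %in% names(m)),
          "metadata must have columns: %s", paste(need, collapse = " "))
  fail_if(anyDuplicated(m$sample) > 0, "duplicate sample in metadata")
  fail_if(any(m$selfing_generations < 1), "selfing_generations must be >= 1")
  m
}

#' Write per-line metadata
#' @param meta data frame with the metadata columns.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_line_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
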