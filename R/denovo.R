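# The de novo filter chain: subtract standing variation, mask regions
# where variants cannot be ascertained, apply quality/depth thresholds,
# then keep homozygous singletons. Each input variant's fate is
# recorded so every removal can be attributed to one filter.

#' Filter configuration for de novo isolation
#'
#' @param min_depth minimum carrier read depth (default 5).
#' @param min_qual minimum variant quality (default 30).
#' @param max_other_lines_carrying number of additional carrier lines
#'   tolerated beyond the first (default 0: strict singleton).
#' @param require_homozygous require the carrier genotype to be
#'   homozygous alternate (default \code{TRUE}).
#' @param allow_family_sharing permit sharing among lines of the same
#'   family (siblings derived from one mutagenized plant); default
#'   \code{FALSE}.
#' @param require_noncarriers_called conservative variant: demand every
#'   non-carrier genotype be a called reference genotype (default
#'   \code{FALSE}; missing non-carrier calls are merely counted).
#' @param drop_position_collisions also remove treatment variants that
#'   share a position (but not alleles) with a known variant (default
#'   \code{FALSE}; such records are flagged instead).
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(min_depth = 5, min_qual = 30,
                          max_other_lines_carrying = 0,
                          require_homozygous = TRUE,
                          allow_family_sharing = FALSE,
                          require_noncarriers_called = FALSE,
                          drop_position_collisions = FALSE) {
  fail_if(min_depth < 0 || min_qual < 0,
          "min_depth and min_qual must be >= 0")
  structure(list(min_depth = min_depth, min_qual = min_qual,
                 max_other_lines_carrying = max_other_lines_carrying,
                 require_homozygous = require_homozygous,
                 allow_family_sharing = allow_family_sharing,
                 require_noncarriers_called = require_noncarriers_called,
                 drop_position_collisions = drop_position_collisions),
            class = "filter_config")
}

#' Remove variants overlapping mask intervals
#'
#' A variant is removed when its reference span (pos .. pos +
#' nchar(ref) - 1) intersects any mask interval.
#'
#' @param x a \code{\link{variant_set}}.
#' @param masks a \code{GRanges} of mask intervals (see
#'   \code{\link{read_mask_bed}}).
#' @return the retained \code{VariantSet}, with attribute
#'   \code{"n_masked_removed"}.
#' @export
apply_masks <- function(x, masks) {
  if (length(x) == 0 || length(masks) == 0) {
    attr(x, "n_masked_removed") <- 0L
    return(x)
  }
  vr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$pos, x$pos + nchar(x$ref) - 1L))
  # suppress the seqlevels warning: contigs with no mask intervals are
  # expected, not an error
  hit <- suppressWarnings(
    IRanges::overlapsAny(vr, masks, ignore.strand = TRUE))
  out <- x[!hit]
  attr(out, "n_masked_removed") <- sum(hit)
  out
}

#' Subtract known (parental and panel) variants
#'
#' Treatment variants identical in (chrom, pos, ref, alt) to any known
#' variant are removed. Treatment variants that merely share a position
#' with a known variant (different alleles) are retained and flagged.
#' All inputs must be normalized (see \code{\link{normalize_variants}}).
#'
#' @param treatment a \code{VariantSet} of treatment-line variants.
#' @param parental,panel \code{VariantSet}s of known variants; either
#'   may be empty.
#' @return the retained \code{VariantSet}, with attributes
#'   \code{"n_known_removed"} and \code{"position_collision"} (logical
#'   per retained variant).
#' @export
subtract_known <- function(treatment, parental = variant_set(),
                           panel = variant_set()) {
  known_key <- c(variant_key(parental), variant_key(panel))
  known_pos <- c(paste(parental$chrom, parental$pos),
                 paste(panel$chrom, panel$pos))
  key <- variant_key(treatment)
  hit <- key %in% known_key
  out <- treatment[!hit]
  coll <- paste(out$chrom, out$pos) %in% known_pos
  attr(out, "n_known_removed") <- sum(hit)
  attr(out, "position_collision") <- coll
  out
}

#' Isolate de novo variants in treatment lines
#'
#' Chains the full filter procedure: subtraction of parental and panel
#' variants, deletion-mask filtering, quality and carrier-depth
#' thresholds, and the carrier rule (variant called non-reference in
#' exactly one line, homozygous by default; optionally shared within a
#' sibling family). Returns a \code{DeNovoSet} with per-line totals and
#' per-variant filter provenance.
#'
#' @param treatment multi-sample \code{VariantSet} over the mutagenized
#'   lines (or a VCF path).
#' @param parental,panel known-variant \code{VariantSet}s (or VCF
#'   paths); pass \code{NULL} for none.
#' @param masks \code{GRanges} of mask intervals (or a BED path);
#'   \code{NULL} for none.
#' @param line_meta data frame from \code{\link{read_line_meta}} (or a
#'   TSV path).
#' @param config a \code{\link{filter_config}}.
#' @param reference optional \code{DNAStringSet}, used when inputs are
#'   file paths.
#' @return an object of class \code{DeNovoSet}: list with elements
#'   \code{variants} (retained \code{VariantSet}), \code{table}
#'   (per-variant data frame with carrier, class, flags),
#'   \code{per_line} (per-line SNP/indel/total counts joined to
#'   metadata, with an outlier flag), \code{provenance} (per input
#'   variant, the filter that removed it or \code{"retained"}) and
#'   \code{filter_counts}.
#' @export
isolate_de_novo <- function(treatment, parental = NULL, panel = NULL,
                            masks = NULL, line_meta, config = filter_config(),
                            reference = NULL) {
  if (is.character(treatment))
    treatment <- read_variants(treatment, reference)
  if (is.character(parental)) parental <- read_variants(parental, reference)
  if (is.character(panel)) panel <- read_variants(panel, reference)
  if (is.character(masks)) masks <- read_mask_bed(masks)
  if (is.character(line_meta)) line_meta <- read_line_meta(line_meta)
  parental <- parental %||% variant_set()
  panel <- panel %||% variant_set()

  fail_if(is.null(treatment$gt), "treatment VariantSet has no genotypes")
  samp <- treatment$samples
  fail_if(!any(samp %in% line_meta$sample),
          "no samples shared between treatment VCF and metadata")
  missing_meta <- setdiff(samp, line_meta$sample)
  fail_if(length(missing_meta) > 0, "metadata missing for sample %s",
          missing_meta[1])
  fam <- setNames(line_meta$family, line_meta$sample)[samp]

  key_all <- variant_key(treatment)
  prov <- setNames(rep("retained", length(treatment)), key_all)

  # 1. subtract known standing variation
  x <- subtract_known(treatment, parental, panel)
  prov[setdiff(key_all, variant_key(x))] <- "known"
  coll <- attr(x, "position_collision")
  if (isTRUE(config$drop_position_collisions) && any(coll)) {
    prov[variant_key(x)[coll]] <- "position_collision"
    x <- x[!coll]
    coll <- rep(FALSE, length(x))
  }

  # 2. deletion masks
  if (!is.null(masks)) {
    before <- variant_key(x)
    keep_coll <- coll
    x2 <- apply_masks(x, masks)
    kept <- variant_key(x2)
    prov[setdiff(before, kept)] <- "masked"
    coll <- keep_coll[match(kept, before)]
    x <- x2
  }

  # 3-4. QC and the carrier rule, evaluated per variant
  keys_x <- variant_key(x)
  keep <- logical(length(x))
  carrier <- character(length(x))
  n_missing_nc <- integer(length(x))
  for (i in seq_len(length(x))) {
    k <- keys_x[i]
    if (is.na(x$qual[i]) || x$qual[i] < config$min_qual) {
      prov[k] <- "low_qual"; next
    }
    dos <- x$gt[i, ]
    carriers <- which(!is.na(dos) & dos >= 1L)
    if (length(carriers) == 0) { prov[k] <- "not_called"; next }
    same_family <- length(carriers) > 1 &&
      config$allow_family_sharing &&
      all(nzchar(fam[carriers])) &&
      length(unique(fam[carriers])) == 1
    if (length(carriers) > 1 + config$max_other_lines_carrying &&
        !same_family) {
      prov[k] <- "multi_carrier"; next
    }
    if (config$require_homozygous && any(dos[carriers] != 2L)) {
      prov[k] <- "heterozygous"; next
    }
    if (!is.null(x$dp)) {
      dpc <- x$dp[i, carriers]
      if (any(is.na(dpc)) || any(dpc < config$min_depth)) {
        prov[k] <- "low_depth"; next
      }
    }
    nc <- setdiff(seq_along(dos), carriers)
    n_missing_nc[i] <- sum(is.na(dos[nc]))
    if (config$require_noncarriers_called && n_missing_nc[i] > 0) {
      prov[k] <- "noncarrier_missing"; next
    }
    keep[i] <- TRUE
    carrier[i] <- samp[carriers[1]]
  }

  kept <- x[keep]
  cls <- classify_variant(kept$ref, kept$alt)
  tab <- cbind(as_variant_frame(kept),
               class = cls$label, signed_length = cls$signed_length,
               carrier = carrier[keep],
               position_collision = coll[keep],
               n_missing_noncarrier = n_missing_nc[keep],
               stringsAsFactors = FALSE)

  per_line <- data.frame(sample = line_meta$sample,
                         stringsAsFactors = FALSE)
  per_line$n_snp <- vapply(per_line$sample, function(s)
    sum(tab$carrier == s & tab$class == "SNP"), integer(1))
  per_line$n_indel <- vapply(per_line$sample, function(s)
    sum(tab$carrier == s & tab$class %in% c("insertion", "deletion")),
    integer(1))
  per_line$n_total <- per_line$n_snp + per_line$n_indel
  med <- stats::median(per_line$n_total)
  per_line$outlier <- med > 0 & per_line$n_total > 3 * med
  per_line <- merge(per_line, line_meta, by = "sample", sort = TRUE)

  structure(list(variants = kept, table = tab, per_line = per_line,
                 provenance = data.frame(key = names(prov),
                                         filter = unname(prov),
                                         stringsAsFactors = FALSE),
                 filter_counts = table(unname(prov)),
                 config = config),
            class = "DeNovoSet")
}

#' @export
print.DeNovoSet <- function(x, ...) {
  cat(sprintf("DeNovoSet: %d retained variants across %d lines\n",
              nrow(x$table), nrow(x$per_line)))
  cat("  filter outcomes:\n")
  fc <- x$filter_counts
  for (nm in names(fc)) cat(sprintf("    %-20s %d\n", nm, fc[[nm]]))
  if (any(x$per_line$outlier))
    cat("  WARNING: per-line counts far above the cohort median for:",
        paste(x$per_line$sample[x$per_line$outlier], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.DeNovoSet <- function(object, ...) {
  per_line_summary(object)
}

#' Partition standing variants by nonreference allele count
#'
#' Rare variants have an allele count of one or two; common variants
#' have three or more. Sites with count zero are excluded from both.
#'
#' @param panel a \code{VariantSet} with genotypes.
#' @return list with \code{rare} and \code{common} \code{VariantSet}s.
#' @export
partition_by_frequency <- function(panel) {
  ac <- nonref_allele_count(panel)
  list(rare = panel[ac >= 1 & ac <= 2], common = panel[ac >= 3])
}
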