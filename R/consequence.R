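# Indel characterisation and a minimal gene-model-based consequence
# classifier. The classifier emits one label per (variant, transcript)
# pair with precedence frameshift/stop_gained/stop_lost/start_lost >
# inframe > missense > splice_region > synonymous > UTR > intron;
# variants within flank_bp of a transcript but outside it are
# upstream/downstream by strand, everything else intergenic. It is not
# a full effect predictor: no regulatory features, no paralog or
# existing-variation lookup.

#' Signed indel length spectrum
#'
#' @param variants a \code{\link{variant_set}} or data frame with
#'   \code{ref}/\code{alt} columns; must contain indel-class records
#'   only.
#' @param cohort_label cohort label.
#' @param display_cap absolute length beyond which \code{plot} does
#'   not draw bars (the histogram itself always retains all lengths).
#' @return an \code{indel_spectrum}: data frame (signed_length, count)
#'   with attributes \code{insertion_fraction}, \code{cohort},
#'   \code{display_cap}.
#' @export
indel_length_spectrum <- function(variants, cohort_label = "cohort",
                                  display_cap = 20) {
  if (is(variants, "VariantSet")) variants <- as_variant_frame(variants)
  fail_if(nrow(variants) == 0, "empty input: no indels")
  cls <- classify_variant(variants$ref, variants$alt)
  fail_if(!all(cls$label %in% c("insertion", "deletion")),
          "indel_length_spectrum expects indel-class variants only")
  tb <- table(cls$signed_length)
  df <- data.frame(signed_length = as.integer(names(tb)),
                   count = as.integer(tb))
  df <- df[order(df$signed_length), , drop = FALSE]
  ins_frac <- sum(df$count[df$signed_length > 0]) / sum(df$count)
  structure(df, class = c("indel_spectrum", "data.frame"),
            insertion_fraction = ins_frac, cohort = cohort_label,
            display_cap = display_cap)
}

#' @export
print.indel_spectrum <- function(x, ...) {
  cat(sprintf("Indel length spectrum (%s): %d indels, %.1f%% insertions\n",
              attr(x, "cohort"), sum(x$count),
              100 * attr(x, "insertion_fraction")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
plot.indel_spectrum <- function(x, ...) {
  cap <- attr(x, "display_cap")
  d <- x[abs(x$signed_length) <= cap, , drop = FALSE]
  graphics::barplot(d$count, names.arg = d$signed_length,
                    xlab = "signed indel length (bp)", ylab = "count",
                    main = attr(x, "cohort"))
  invisible(x)
}

#' Base identity of single-base-pair indels
#'
#' For VCF-style 1-bp indels (shared anchor base), tallies the
#' non-anchor base per direction.
#'
#' @param variants a \code{VariantSet} or data frame of 1-bp indels
#'   only (anything else is an error).
#' @return list of two named integer vectors, \code{inserted} and
#'   \code{deleted}, over A/C/G/T.
#' @export
single_bp_identity <- function(variants) {
  if (is(variants, "VariantSet")) variants <- as_variant_frame(variants)
  cls <- classify_variant(variants$ref, variants$alt)
  fail_if(!all(abs(cls$signed_length) == 1),
          "single_bp_identity accepts 1-bp indels only")
  del <- cls$signed_length == -1
  del_base <- substr(variants$ref[del], 2, 2)
  ins_base <- substr(variants$alt[!del], 2, 2)
  tally <- function(b) {
    out <- setNames(integer(4), BASES)
    tb <- table(factor(b, levels = BASES))
    out[names(tb)] <- as.integer(tb)
    out
  }
  list(inserted = tally(ins_base), deleted = tally(del_base))
}

## --- transcript machinery ------------------------------------------

# Precompute one transcript's anatomy: sorted exon/CDS intervals,
# intron gaps, and the coding-order vector of genomic CDS positions.
build_tx_index <- function(gm) {
  lapply(seq_len(nrow(gm$transcripts)), function(i) {
    tx <- gm$transcripts[i, ]
    ex <- gm$exons[gm$exons$tx_id == tx$tx_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- gm$cds[gm$cds$tx_id == tx$tx_id, , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    introns <- if (nrow(ex) > 1)
      data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
    else data.frame(start = integer(0), end = integer(0))
    cds_pos <- unlist(mapply(seq, cd$start, cd$end, SIMPLIFY = FALSE))
    if (tx$strand == "-") cds_pos <- rev(cds_pos)
    list(tx = tx, exons = ex, cds = cd, introns = introns,
         cds_pos = as.integer(cds_pos))
  })
}

in_intervals <- function(p, iv) {
  any(iv$start <= p & p <= iv$end)
}

base_at <- function(contig_chr, pos) substr(contig_chr, pos, pos)

# Translate one codon (standard genetic code).
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# classify one SNP against one transcript's index; returns a label
classify_snp_tx <- function(pos, ref, alt, ti, contig_chr,
                            splice_exonic, splice_intronic) {
  strand <- ti$tx$strand
  splice_exon_hit <- function(p) {
    if (nrow(ti$introns) == 0) return(FALSE)
    # exon bases within splice_exonic of an exon/intron junction
    ends <- ti$exons$end[-nrow(ti$exons)]     # junctions into introns
    starts <- ti$exons$start[-1]
    any(p >= ends - splice_exonic + 1L & p <= ends) ||
      any(p <= starts + splice_exonic - 1L & p >= starts)
  }
  if (length(ti$cds_pos) && pos %in% ti$cds_pos) {
    idx <- match(pos, ti$cds_pos)
    ci <- (idx - 1L) %/% 3L
    cod_pos <- ti$cds_pos[(3L * ci + 1L):(3L * ci + 3L)]
    get_base <- function(p) {
      b <- base_at(contig_chr, p)
      if (strand == "-") complement_chr(b) else b
    }
    ref_cod <- vapply(cod_pos, get_base, character(1))
    alt_cod <- ref_cod
    alt_cod[match(pos, cod_pos)] <-
      if (strand == "-") complement_chr(alt) else alt
    aa_ref <- codon_aa(paste(ref_cod, collapse = ""))
    aa_alt <- codon_aa(paste(alt_cod, collapse = ""))
    if (ci == 0L && !identical(paste(alt_cod, collapse = ""), "ATG"))
      return("start_lost")
    if (aa_ref != "*" && aa_alt == "*") return("stop_gained")
    if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
    if (aa_ref != aa_alt) return("missense")
    if (splice_exon_hit(pos)) return("splice_region")
    return("synonymous")
  }
  if (in_intervals(pos, ti$introns)) {
    w <- which(ti$introns$start <= pos & pos <= ti$introns$end)
    depth <- min(pos - ti$introns$start[w], ti$introns$end[w] - pos)
    if (depth < splice_intronic) return("splice_region")
    return("intron")
  }
  if (in_intervals(pos, ti$exons)) {
    if (splice_exon_hit(pos)) return("splice_region")
    return(utr_side(pos, ti))
  }
  NA_character_
}

# which UTR a non-coding exonic position belongs to
utr_side <- function(pos, ti) {
  if (length(ti$cds_pos) == 0) return("intron")  # non-coding transcript
  cds_lo <- min(ti$cds_pos); cds_hi <- max(ti$cds_pos)
  before <- pos < cds_lo
  if (ti$tx$strand == "+") {
    if (before) "5' UTR" else "3' UTR"
  } else {
    if (before) "3' UTR" else "5' UTR"
  }
}

# classify one indel against one transcript
classify_indel_tx <- function(pos, ref, alt, ti, splice_exonic,
                              splice_intronic) {
  sl <- nchar(alt) - nchar(ref)
  if (sl < 0) {
    affected <- (pos + 1L):(pos + abs(sl))      # deleted bases
    net <- -sum(affected %in% ti$cds_pos)
  } else {
    # insertion lands between pos and pos+1
    inside_cds <- (pos %in% ti$cds_pos) && ((pos + 1L) %in% ti$cds_pos)
    net <- if (inside_cds) sl else 0L
    affected <- c(pos, pos + 1L)
  }
  if (net %% 3L != 0L) return("frameshift")
  if (net != 0L)
    return(if (sl > 0) "inframe_insertion" else "inframe_deletion")
  # no CDS length change: classify by position
  splice <- any(vapply(affected, function(p) {
    if (nrow(ti$introns) == 0) return(FALSE)
    w <- which(ti$introns$start <= p & p <= ti$introns$end)
    intr <- length(w) > 0 &&
      min(p - ti$introns$start[w], ti$introns$end[w] - p) < splice_intronic
    ends <- ti$exons$end[-nrow(ti$exons)]; starts <- ti$exons$start[-1]
    exn <- any(p >= ends - splice_exonic + 1L & p <= ends) ||
      any(p <= starts + splice_exonic - 1L & p >= starts)
    intr || exn
  }, logical(1)))
  if (splice) return("splice_region")
  ex_hit <- affected[vapply(affected, in_intervals, logical(1),
                            iv = ti$exons)]
  if (length(ex_hit)) return(utr_side(ex_hit[1], ti))
  if (any(vapply(affected, in_intervals, logical(1), iv = ti$introns)))
    return("intron")
  NA_character_
}

#' Classify variant consequences against gene models
#'
#' @param variants a \code{\link{variant_set}} or data frame with
#'   \code{chrom, pos, ref, alt}.
#' @param gm a \code{\link{gene_models}} object (validated).
#' @param reference a \code{DNAStringSet} (codon lookup).
#' @param flank_bp distance within which a variant outside a
#'   transcript is labelled upstream/downstream (default 5000).
#' @param splice_exonic,splice_intronic splice-region extent: exonic
#'   bases (default 3) and intronic bases (default 8) from each
#'   exon/intron junction. Splice donor/acceptor sites are folded into
#'   \code{splice_region}.
#' @return data frame with one row per (variant, transcript) overlap
#'   pair plus one row (transcript \code{NA}) per variant with no
#'   transcript within range; columns \code{chrom, pos, ref, alt,
#'   transcript, consequence}.
#' @export
classify_consequence <- function(variants, gm, reference,
                                 flank_bp = 5000, splice_exonic = 3,
                                 splice_intronic = 8) {
  if (is(variants, "VariantSet")) variants <- as_variant_frame(variants)
  validate_gene_models(gm)
  idx <- build_tx_index(gm)
  seqs <- as.character(reference)
  tx_chrom <- gm$transcripts$chrom
  tx_start <- gm$transcripts$start
  tx_end <- gm$transcripts$end

  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    ch <- variants$chrom[i]; p <- variants$pos[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    span_end <- p + nchar(ref) - 1L
    cand <- which(tx_chrom == ch & tx_start - flank_bp <= span_end &
                    p <= tx_end + flank_bp)
    recs <- list()
    for (j in cand) {
      ti <- idx[[j]]
      overl <- p <= ti$tx$end && span_end >= ti$tx$start
      if (overl) {
        lab <- if (nchar(ref) == 1 && nchar(alt) == 1)
          classify_snp_tx(p, ref, alt, ti, seqs[[ch]],
                          splice_exonic, splice_intronic)
        else if (nchar(ref) != nchar(alt))
          classify_indel_tx(p, ref, alt, ti, splice_exonic,
                            splice_intronic)
        else NA_character_   # MNP/complex: not classified
      } else {
        before <- span_end < ti$tx$start
        lab <- if (ti$tx$strand == "+") {
          if (before) "upstream" else "downstream"
        } else {
          if (before) "downstream" else "upstream"
        }
      }
      if (!is.na(lab))
        recs[[length(recs) + 1L]] <-
          data.frame(chrom = ch, pos = p, ref = ref, alt = alt,
                     transcript = ti$tx$tx_id, consequence = lab,
                     stringsAsFactors = FALSE)
    }
    if (length(recs) == 0)
      recs[[1]] <- data.frame(chrom = ch, pos = p, ref = ref,
                              alt = alt, transcript = NA_character_,
                              consequence = "intergenic",
                              stringsAsFactors = FALSE)
    rows[[i]] <- do.call(rbind, recs)
  }
  do.call(rbind, rows)
}

#' Aggregate consequence records into a per-class summary
#'
#' @param records output of \code{\link{classify_consequence}}.
#' @param cohort_label cohort label.
#' @return data frame \code{(consequence, count, proportion)}; the
#'   proportion column is in percent and sums to 100.
#' @export
consequence_summary <- function(records, cohort_label = "cohort") {
  tb <- table(records$consequence)
  df <- data.frame(consequence = names(tb), count = as.integer(tb),
                   stringsAsFactors = FALSE)
  df$proportion <- 100 * df$count / sum(df$count)
  attr(df, "cohort") <- cohort_label
  df
}

# class labels counted as coding when computing frameshift fractions
CODING_CLASSES <- c("stop_gained", "frameshift", "stop_lost",
                    "start_lost", "inframe_insertion",
                    "inframe_deletion", "protein_altering", "missense",
                    "synonymous", "start_retained", "stop_retained",
                    "coding_sequence")

#' Frameshift share of coding variant consequences
#'
#' The frameshift count divided by the sum over all coding consequence
#' classes, in percent. Label matching is case-insensitive so summary
#' tables with display capitalisation are accepted.
#'
#' @param summary a data frame with \code{consequence} and
#'   \code{count} columns, or a named numeric vector of class counts.
#' @return percentage of coding consequences that are frameshifts.
#' @export
frameshift_fraction_of_coding <- function(summary) {
  if (is.data.frame(summary)) {
    counts <- setNames(summary$count, summary$consequence)
  } else counts <- summary
  names(counts) <- tolower(names(counts))
  coding <- counts[names(counts) %in% CODING_CLASSES]
  fail_if(sum(coding) == 0, "no coding consequences in summary")
  fs <- if ("frameshift" %in% names(counts)) counts[["frameshift"]] else 0
  100 * fs / sum(coding)
}
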