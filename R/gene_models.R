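# Gene models: a light container over GFF3 gene/mRNA/exon/CDS records.
# All coordinates 1-based inclusive on the reference; UTRs are derived
# (exon minus CDS) rather than stored.

#' Construct a GeneModels object
#'
#' @param transcripts data frame with columns \code{tx_id, gene_id,
#'   chrom, strand, start, end}.
#' @param exons data frame with columns \code{tx_id, start, end}.
#' @param cds data frame with columns \code{tx_id, start, end, phase}.
#' @return an object of class \code{GeneModels}.
#' @export
gene_models <- function(transcripts, exons, cds) {
  gm <- structure(list(transcripts = transcripts, exons = exons,
                       cds = cds), class = "GeneModels")
  validate_gene_models(gm)
  gm
}

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d transcripts, %d exons, %d CDS segments\n",
              nrow(x$transcripts), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Validate a GeneModels object
#'
#' Checks that per-transcript exons are sorted and non-overlapping and
#' that every CDS segment lies within an exon. Malformed models are an
#' error.
#'
#' @param gm a \code{GeneModels} object.
#' @return \code{gm}, invisibly.
#' @export
validate_gene_models <- function(gm) {
  tx <- gm$transcripts
  need <- c("tx_id", "gene_id", "chrom", "strand", "start", "end")
  fail_if(!all(need %in% names(tx)), "transcripts table malformed")
  fail_if(!all(tx$strand %in% c("+", "-")), "strand must be + or -")
  for (id in tx$tx_id) {
    ex <- gm$exons[gm$exons$tx_id == id, , drop = FALSE]
    fail_if(nrow(ex) == 0, "transcript %s has no exons", id)
    ex <- ex[order(ex$start), , drop = FALSE]
    fail_if(any(ex$end < ex$start), "exon with end < start in %s", id)
    if (nrow(ex) > 1)
      fail_if(any(ex$start[-1] <= ex$end[-nrow(ex)]),
              "overlapping exons in transcript %s", id)
    cd <- gm$cds[gm$cds$tx_id == id, , drop = FALSE]
    for (j in seq_len(nrow(cd))) {
      inside <- any(ex$start <= cd$start[j] & cd$end[j] <= ex$end)
      fail_if(!inside, "CDS segment outside exons in transcript %s", id)
    }
  }
  invisible(gm)
}

#' Read gene models from a GFF3 file
#'
#' Accepts gene / mRNA / exon / CDS features with standard ID/Parent
#' attributes.
#'
#' @param path GFF3 file path.
#' @return a \code{\link{gene_models}} object.
#' @export
read_gene_models <- function(path) {
  fail_if(!file.exists(path), "no such file: %s", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1]] else NA_character_, character(1))
  is_tx <- type %in% c("mRNA", "transcript")
  tx <- data.frame(
    tx_id = as.character(gr$ID[is_tx]),
    gene_id = first_parent(gr$Parent[is_tx]),
    chrom = as.character(GenomicRanges::seqnames(gr)[is_tx]),
    strand = as.character(GenomicRanges::strand(gr)[is_tx]),
    start = GenomicRanges::start(gr)[is_tx],
    end = GenomicRanges::end(gr)[is_tx],
    stringsAsFactors = FALSE)
  ex_i <- type == "exon"
  exons <- data.frame(
    tx_id = first_parent(gr$Parent[ex_i]),
    start = GenomicRanges::start(gr)[ex_i],
    end = GenomicRanges::end(gr)[ex_i],
    stringsAsFactors = FALSE)
  cd_i <- type == "CDS"
  phase <- if ("phase" %in% names(S4Vectors::mcols(gr)))
    as.integer(as.character(gr$phase[cd_i])) else rep(0L, sum(cd_i))
  cds <- data.frame(
    tx_id = first_parent(gr$Parent[cd_i]),
    start = GenomicRanges::start(gr)[cd_i],
    end = GenomicRanges::end(gr)[cd_i],
    phase = ifelse(is.na(phase), 0L, phase),
    stringsAsFactors = FALSE)
  gene_models(tx, exons, cds)
}

#' Write gene models to GFF3
#' @param gm a \code{GeneModels} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  lines <- "##gff-version 3"
  tx <- gm$transcripts[order(gm$transcripts$chrom,
                             gm$transcripts$start), , drop = FALSE]
  for (g in unique(tx$gene_id)) {
    gtx <- tx[tx$gene_id == g, , drop = FALSE]
    lines <- c(lines, paste(gtx$chrom[1], "fnmut", "gene",
                            min(gtx$start), max(gtx$end), ".",
                            gtx$strand[1], ".",
                            sprintf("ID=%s", g), sep = "\t"))
    for (i in seq_len(nrow(gtx))) {
      id <- gtx$tx_id[i]
      lines <- c(lines, paste(gtx$chrom[i], "fnmut", "mRNA",
                              gtx$start[i], gtx$end[i], ".",
                              gtx$strand[i], ".",
                              sprintf("ID=%s;Parent=%s", id, g),
                              sep = "\t"))
      ex <- gm$exons[gm$exons$tx_id == id, , drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      for (j in seq_len(nrow(ex)))
        lines <- c(lines, paste(gtx$chrom[i], "fnmut", "exon",
                                ex$start[j], ex$end[j], ".",
                                gtx$strand[i], ".",
                                sprintf("ID=%s.exon%d;Parent=%s",
                                        id, j, id), sep = "\t"))
      cd <- gm$cds[gm$cds$tx_id == id, , drop = FALSE]
      cd <- cd[order(cd$start), , drop = FALSE]
      for (j in seq_len(nrow(cd)))
        lines <- c(lines, paste(gtx$chrom[i], "fnmut", "CDS",
                                cd$start[j], cd$end[j], ".",
                                gtx$strand[i], cd$phase[j],
                                sprintf("ID=%s.cds%d;Parent=%s",
                                        id, j, id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
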