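# Flanking-sequence context of SNPs. Windows are strand-normalized so
# the central reference base is A or C (reverse-complementing the
# whole window otherwise), and scored against a resampled null built
# from nearby positions carrying the same reference base, by relative
# entropy (Kullback-Leibler divergence, bits) per flanking offset.

#' Configuration for context extraction and the resampled null
#'
#' @param k flank width in bases on each side (default 2).
#' @param W half-width of the null-sampling window in bases (default
#'   50); must exceed \code{k}.
#' @param seed RNG seed for the null draw; a fixed seed gives an
#'   identical null sample.
#' @param n_null_per_variant null positions drawn per focal SNP
#'   (default 1).
#' @return a \code{context_config} list.
#' @export
context_config <- function(k = 2, W = 50, seed = NULL,
                           n_null_per_variant = 1) {
  fail_if(k < 1, "k must be >= 1")
  fail_if(W <= k, "W must exceed k")
  structure(list(k = k, W = W, seed = seed,
                 n_null_per_variant = n_null_per_variant),
            class = "context_config")
}

offset_labels <- function(k) {
  c(paste0("-", k:1), paste0("+", 1:k))
}

new_context_windows <- function(bases, ref, alt, flipped, chrom, pos,
                                k, excluded) {
  cls <- if (length(ref)) collapse_class(ref, alt) else character(0)
  structure(list(bases = bases, ref = ref, alt = alt,
                 flipped = flipped, chrom = chrom, pos = pos,
                 class = cls, k = k, excluded = excluded),
            class = "context_windows")
}

#' @export
print.context_windows <- function(x, ...) {
  cat(sprintf("context_windows: %d windows (k = %d)\n",
              length(x$pos), x$k))
  if (length(x$class))
    cat("  classes:", paste(names(table(x$class)), table(x$class),
                            sep = "=", collapse = ", "), "\n")
  ex <- x$excluded
  if (sum(unlist(ex)) > 0)
    cat(sprintf("  excluded: %d edge, %d overlapping-variant, %d with N\n",
                ex$edge, ex$overlap, ex$n_base))
  invisible(x)
}

#' Number of context windows
#' @param x a \code{context_windows} object.
#' @export
n_windows <- function(x) length(x$pos)

# core window extraction shared by observed and null sets
extract_window_at <- function(contig_chr, pos, k) {
  substring(contig_chr, pos - k, pos + k)
}

flip_window <- function(win) {
  revcomp_chr(win)
}

window_to_row <- function(win, k) {
  b <- strsplit(win, "", fixed = TRUE)[[1]]
  b[-(k + 1)]
}

#' Extract strand-normalized flanking windows around SNPs
#'
#' For each SNP, a window of 2k+1 reference bases centred on the
#' variant is taken; windows whose central reference base is G or T
#' are reverse-complemented (alt base complemented, upstream and
#' downstream exchanged) so the central base is always A or C. Windows
#' truncated by a contig edge, containing another variant position, or
#' containing a non-ACGT base are excluded and counted. Indel input is
#' rejected: the local context of an indel is not directly observable
#' because multiple equiprobable alignments of the event exist.
#'
#' @param snvs a \code{\link{variant_set}} of SNPs (REF alleles are
#'   verified against the reference; a mismatch is fatal).
#' @param reference a \code{DNAStringSet}.
#' @param config a \code{\link{context_config}}.
#' @return a \code{context_windows} object; element \code{bases} is a
#'   windows x offsets character matrix with columns \code{-k..-1,
#'   +1..+k} in 5'->3' orientation after strand normalization.
#' @export
extract_flanks <- function(snvs, reference, config = context_config()) {
  cls <- classify_variant(snvs$ref, snvs$alt)
  fail_if(any(cls$label != "SNP"),
          "extract_flanks accepts SNPs only; indel context is undefined")
  check_ref_alleles(snvs, reference)
  k <- config$k
  seqs <- as.character(reference)
  lens <- setNames(nchar(seqs), names(seqs))
  pos_by_chrom <- split(snvs$pos, snvs$chrom)

  n <- length(snvs)
  keep <- logical(n); winstr <- character(n); flipped <- logical(n)
  ex <- list(edge = 0L, overlap = 0L, n_base = 0L)
  for (i in seq_len(n)) {
    ch <- snvs$chrom[i]; p <- snvs$pos[i]
    if (p - k < 1 || p + k > lens[[ch]]) { ex$edge <- ex$edge + 1L; next }
    others <- pos_by_chrom[[ch]]
    if (any(others != p & abs(others - p) <= k)) {
      ex$overlap <- ex$overlap + 1L; next
    }
    w <- extract_window_at(seqs[[ch]], p, k)
    if (grepl("[^ACGT]", w)) { ex$n_base <- ex$n_base + 1L; next }
    fl <- snvs$ref[i] %in% c("G", "T")
    if (fl) w <- flip_window(w)
    keep[i] <- TRUE; winstr[i] <- w; flipped[i] <- fl
  }
  idx <- which(keep)
  bases <- if (length(idx))
    t(vapply(winstr[idx], window_to_row, character(2 * k), k = k))
  else matrix(character(0), 0, 2 * k)
  dimnames(bases) <- list(NULL, offset_labels(k))
  ref <- ifelse(flipped[idx], complement_chr(snvs$ref[idx]),
                snvs$ref[idx])
  alt <- ifelse(flipped[idx], complement_chr(snvs$alt[idx]),
                snvs$alt[idx])
  new_context_windows(bases, ref, alt, flipped[idx],
                      snvs$chrom[idx], snvs$pos[idx], k, ex)
}

#' Sample null context windows near each focal SNP
#'
#' For each focal SNP, positions within ±W of the site whose reference
#' base equals the focal (pre-strand-flip) reference base are eligible,
#' excluding the focal site itself, every other variant position, and
#' positions whose window would not fit or would contain a non-ACGT
#' base. \code{n_null_per_variant} positions are drawn uniformly (with
#' replacement across draws) and their windows extracted under the same
#' strand-normalization rule; each null window inherits the focal
#' variant's mutation class so class-filtered profiles compare like
#' with like. Focal SNPs with no eligible position are skipped and
#' counted.
#'
#' @inheritParams extract_flanks
#' @return a \code{context_windows} object with attribute
#'   \code{"n_skipped"}.
#' @export
sample_null_windows <- function(snvs, reference,
                                config = context_config()) {
  cls <- classify_variant(snvs$ref, snvs$alt)
  fail_if(any(cls$label != "SNP"), "null sampling is defined for SNPs")
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$k; W <- config$W
  seqs <- as.character(reference)
  lens <- setNames(nchar(seqs), names(seqs))
  var_pos <- lapply(split(snvs$pos, snvs$chrom), unique)

  bases_l <- list(); refv <- character(0); altv <- character(0)
  flv <- logical(0); chv <- character(0); pv <- integer(0)
  clv <- character(0)
  n_skipped <- 0L
  for (i in seq_len(length(snvs))) {
    ch <- snvs$chrom[i]; p <- snvs$pos[i]; b <- snvs$ref[i]
    lo <- max(k + 1, p - W); hi <- min(lens[[ch]] - k, p + W)
    if (lo > hi) { n_skipped <- n_skipped + 1L; next }
    seg <- substring(seqs[[ch]], lo, hi)
    cand <- lo - 1L + which(strsplit(seg, "", fixed = TRUE)[[1]] == b)
    cand <- setdiff(cand, c(p, var_pos[[ch]]))
    if (length(cand) == 0) { n_skipped <- n_skipped + 1L; next }
    draws <- cand[sample.int(length(cand), config$n_null_per_variant,
                             replace = TRUE)]
    for (q in draws) {
      w <- extract_window_at(seqs[[ch]], q, k)
      if (grepl("[^ACGT]", w)) next
      fl <- b %in% c("G", "T")
      if (fl) w <- flip_window(w)
      bases_l[[length(bases_l) + 1L]] <- window_to_row(w, k)
      refv <- c(refv, if (fl) complement_chr(b) else b)
      altv <- c(altv, if (fl) complement_chr(snvs$alt[i]) else snvs$alt[i])
      flv <- c(flv, fl); chv <- c(chv, ch); pv <- c(pv, q)
    }
  }
  bases <- if (length(bases_l)) do.call(rbind, bases_l)
           else matrix(character(0), 0, 2 * k)
  dimnames(bases) <- list(NULL, offset_labels(k))
  out <- new_context_windows(bases, refv, altv, flv, chv, pv, k,
                             list(edge = 0L, overlap = 0L, n_base = 0L))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Relative-entropy context profile
#'
#' Compares base composition at each flanking offset between observed
#' and null windows, after filtering both to one strand-collapsed
#' class. Frequencies use an additive pseudocount (default 0.5 per
#' base). The per-offset relative entropy is
#' \eqn{RE_j = \sum_b p_j(b) \log_2(p_j(b)/q_j(b))}, non-negative; the
#' signed per-base contribution \eqn{p_j(b)\log_2(p_j(b)/q_j(b))} is
#' positive for overrepresented and negative for underrepresented
#' bases.
#'
#' @param observed,null \code{context_windows} objects.
#' @param class_filter a collapsed class label (e.g. \code{"C>T*"}) or
#'   \code{NULL} for all classes pooled.
#' @param pseudocount added to each base count before normalization
#'   (default 0.5); set 0 to recompute from raw counts.
#' @return an \code{re_profile} object: per offset, observed and null
#'   frequencies, raw counts, total RE in bits and signed per-base
#'   contributions.
#' @export
relative_entropy_profile <- function(observed, null,
                                     class_filter = NULL,
                                     pseudocount = 0.5) {
  k <- observed$k
  fail_if(null$k != k, "observed and null windows use different k")
  ob <- observed$bases; nb <- null$bases
  if (!is.null(class_filter)) {
    ob <- ob[observed$class == class_filter, , drop = FALSE]
    nb <- nb[null$class == class_filter, , drop = FALSE]
  }
  fail_if(nrow(ob) == 0 || nrow(nb) == 0,
          "no windows left after class filtering")
  offs <- offset_labels(k)
  count_mat <- function(m) {
    t(vapply(offs, function(o)
      vapply(BASES, function(b) sum(m[, o] == b), numeric(1)),
      numeric(4)))
  }
  co <- count_mat(ob); cn <- count_mat(nb)
  p <- (co + pseudocount) / rowSums(co + pseudocount)
  q <- (cn + pseudocount) / rowSums(cn + pseudocount)
  contrib <- p * log2(p / q)
  contrib[p == 0] <- 0
  re <- rowSums(contrib)
  structure(list(offsets = offs, p = p, q = q,
                 counts_obs = co, counts_null = cn,
                 contrib = contrib, re_bits = setNames(re, offs),
                 n_obs = nrow(ob), n_null = nrow(nb),
                 pseudocount = pseudocount,
                 class = class_filter %||% "all"),
            class = "re_profile")
}

#' @export
print.re_profile <- function(x, ...) {
  cat(sprintf("Relative-entropy profile, class %s (%d observed, %d null windows)\n",
              x$class, x$n_obs, x$n_null))
  df <- data.frame(offset = x$offsets,
                   RE_bits = round(x$re_bits, 4),
                   round(x$contrib, 4))
  names(df)[3:6] <- BASES
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bar-logo plot of an RE profile
#'
#' Per offset, signed per-base contributions: overrepresented bases
#' above the axis, underrepresented below.
#' @param x an \code{re_profile}.
#' @param ... ignored.
#' @export
plot.re_profile <- function(x, ...) {
  m <- t(x$contrib)
  pos <- pmax(m, 0); neg <- pmin(m, 0)
  ylim <- range(c(colSums(pos), colSums(neg)))
  graphics::barplot(pos, ylim = ylim * 1.1, col = 2:5,
                    names.arg = x$offsets,
                    ylab = "signed RE contribution (bits)",
                    xlab = "offset from variant",
                    main = sprintf("context profile, %s", x$class))
  graphics::barplot(neg, add = TRUE, col = 2:5, names.arg = NA)
  graphics::legend("topright", legend = BASES, fill = 2:5, bty = "n")
  invisible(x)
}

#' Permutation null for RE profiles
#'
#' Shuffles window labels between the observed and null sets and
#' recomputes the per-offset relative entropy, giving a reference
#' distribution for RE magnitudes expected when context carries no
#' signal.
#'
#' @param observed,null \code{context_windows} objects (already
#'   filtered as desired).
#' @param class_filter as in \code{\link{relative_entropy_profile}}.
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed.
#' @param pseudocount see \code{\link{relative_entropy_profile}}.
#' @return matrix (n_perm x offsets) of permuted RE values in bits.
#' @export
re_permutation_null <- function(observed, null, class_filter = NULL,
                                n_perm = 200, seed = 1,
                                pseudocount = 0.5) {
  ob <- observed$bases; nb <- null$bases
  if (!is.null(class_filter)) {
    ob <- ob[observed$class == class_filter, , drop = FALSE]
    nb <- nb[null$class == class_filter, , drop = FALSE]
  }
  pool <- rbind(ob, nb)
  n_o <- nrow(ob)
  k <- observed$k
  set.seed(seed)
  out <- matrix(NA_real_, n_perm, 2 * k,
                dimnames = list(NULL, offset_labels(k)))
  mk <- function(m) {
    w <- new_context_windows(m, rep("C", nrow(m)), rep("T", nrow(m)),
                             rep(FALSE, nrow(m)), rep("x", nrow(m)),
                             seq_len(nrow(m)), k,
                             list(edge = 0L, overlap = 0L, n_base = 0L))
    w
  }
  for (r in seq_len(n_perm)) {
    idx <- sample.int(nrow(pool), n_o)
    pr <- relative_entropy_profile(mk(pool[idx, , drop = FALSE]),
                                   mk(pool[-idx, , drop = FALSE]),
                                   pseudocount = pseudocount)
    out[r, ] <- pr$re_bits
  }
  out
}

#' Write context windows as a FASTA file
#'
#' One sequence of 2k+1 bases per window (central base included),
#' header \code{chrom:pos:class}.
#'
#' @param windows a \code{context_windows} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_context_fasta <- function(windows, path) {
  k <- windows$k
  seqs <- vapply(seq_len(n_windows(windows)), function(i) {
    paste0(paste(windows$bases[i, 1:k], collapse = ""),
           windows$ref[i],
           paste(windows$bases[i, (k + 1):(2 * k)], collapse = ""))
  }, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste(windows$chrom, windows$pos, windows$class, sep = ":")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Genome k-mer composition
#'
#' Counts all contiguous k-mers over the A/C/G/T alphabet across all
#' contigs (overlapping windows; windows containing other letters are
#' skipped), via \code{\link[Biostrings]{oligonucleotideFrequency}}.
#'
#' @param reference a \code{DNAStringSet}.
#' @param k word size (>= 1).
#' @param both_strands also count the reverse complement of each
#'   window (default \code{FALSE}).
#' @return data frame with columns \code{kmer, count, frequency};
#'   frequencies sum to 1.
#' @export
kmer_composition <- function(reference, k, both_strands = FALSE) {
  fail_if(k < 1, "k must be >= 1")
  fail_if(all(Biostrings::width(reference) < k),
          "k exceeds the length of every contig")
  cnt <- colSums(Biostrings::oligonucleotideFrequency(reference,
                                                      width = k))
  if (both_strands) {
    rc <- revcomp_chr(names(cnt))
    cnt <- cnt + cnt[rc]
  }
  data.frame(kmer = names(cnt), count = as.numeric(cnt),
             frequency = as.numeric(cnt) / sum(cnt),
             stringsAsFactors = FALSE)
}
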