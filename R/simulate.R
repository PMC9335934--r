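# Synthetic study generator with planted truth. Emulates the
# statistical structure the analysis assumes: a reference at ~34% GC,
# parental differences from the reference plus deletion masks,
# a diversity panel whose allele-frequency spectrum spans rare and
# common variants, and treatment lines carrying homozygous singleton
# de novo SNPs (configurable six-class spectrum with a CpG-conditional
# boost for C>T*) and indels (deletion-skewed, 1-bp-dominated signed
# lengths with an A/T bias in single-base events). Optional noise
# layers plant exactly the artefacts the filter chain must remove.
# Everything is deterministic under a fixed seed.

#' Simulation configuration
#'
#' Defaults are the cohort conditions the package is designed around:
#' 27 treatment lines with per-line Poisson means of 53 SNPs and 32
#' indels, a 30-line diversity panel, and a scaled-down 2 x 2 Mb
#' genome at 34\% GC so a full study runs at desk scale.
#'
#' @param seed master RNG seed; all stages derive their streams from
#'   it.
#' @param contigs named integer vector of contig lengths.
#' @param gc_fraction genomic GC content (default 0.34).
#' @param parental_snp_per_kb,parental_indel_per_kb parental variant
#'   densities (defaults 1.5 and 0.25 per kb).
#' @param masked_fraction fraction of the genome covered by deletion
#'   masks (default 0.038).
#' @param mask_mean_len mean mask interval length in bases.
#' @param panel_n_lines diversity-panel size (default 30).
#' @param panel_snp_per_kb,panel_indel_per_kb panel site densities.
#' @param panel_insertion_fraction insertion share among panel indels
#'   (default 0.468).
#' @param fn_n_lines treatment-cohort size (default 27).
#' @param lambda_snp,lambda_indel per-line Poisson means for de novo
#'   SNPs (53) and indels (32).
#' @param class_probs named probabilities over the six collapsed
#'   classes (C>T* largest by default).
#' @param cpg_boost multiplicative preference for planting C>T* events
#'   in a CpG context (default 3).
#' @param deletion_fraction share of de novo indels that are deletions
#'   (default 0.715).
#' @param indel_geom_p geometric decay of indel length beyond 1 bp
#'   (default 0.6; P(len 1) = 0.6).
#' @param max_indel length cap for planted indels.
#' @param at_bias_1bp probability a 1-bp indel involves A or T
#'   (default 0.8).
#' @param mean_depth Poisson mean of simulated read depths.
#' @param het_rate,low_depth_rate noise rates (per planted variant) of
#'   spurious heterozygous calls and of low-coverage artefacts.
#' @param n_heterogeneity number of heterogeneity variants shared
#'   hom-alt by several non-sibling lines.
#' @param site_margin minimum spacing in bases between planted events
#'   and any other feature.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1,
                       contigs = c(chr1 = 2e6, chr2 = 2e6),
                       gc_fraction = 0.34,
                       parental_snp_per_kb = 1.5,
                       parental_indel_per_kb = 0.25,
                       masked_fraction = 0.038,
                       mask_mean_len = 5000,
                       panel_n_lines = 30,
                       panel_snp_per_kb = 2,
                       panel_indel_per_kb = 0.35,
                       panel_insertion_fraction = 0.468,
                       fn_n_lines = 27,
                       lambda_snp = 53,
                       lambda_indel = 32,
                       class_probs = c("C>T*" = 0.458, "A>G*" = 0.220,
                                       "C>A*" = 0.100, "C>G*" = 0.055,
                                       "A>T*" = 0.090, "A>C*" = 0.077),
                       cpg_boost = 3,
                       deletion_fraction = 0.715,
                       indel_geom_p = 0.6,
                       max_indel = 50,
                       at_bias_1bp = 0.8,
                       mean_depth = 30,
                       het_rate = 0,
                       low_depth_rate = 0,
                       n_heterogeneity = 0,
                       site_margin = 60) {
  fail_if(abs(sum(class_probs) - 1) > 1e-9,
          "class_probs must sum to 1")
  fail_if(!setequal(names(class_probs), COLLAPSED_CLASSES),
          "class_probs must be named by the six collapsed classes")
  fail_if(gc_fraction < 0 || gc_fraction > 1, "gc_fraction in [0,1]")
  fail_if(masked_fraction < 0 || masked_fraction >= 1,
          "masked_fraction in [0,1)")
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# base sampling probabilities at a given GC
base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' Generate a random reference genome
#'
#' I.i.d. bases with \code{P(G) + P(C) = gc_fraction}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{DNAStringSet}.
#' @export
simulate_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  p <- base_probs(config$gc_fraction)
  seqs <- vapply(config$contigs, function(len) {
    paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(config$contigs)
  out
}

## --- internal char-vector genome handle ----------------------------

genome_chars <- function(reference) {
  lapply(as.character(reference), function(s)
    strsplit(s, "", fixed = TRUE)[[1]])
}

chars_to_dss <- function(chars) {
  out <- Biostrings::DNAStringSet(vapply(chars, paste, character(1),
                                         collapse = ""))
  names(out) <- names(chars)
  out
}

# blocked-position bookkeeping: one logical vector per contig
new_blocked <- function(contigs, edge = 100L) {
  lapply(contigs, function(len) {
    b <- logical(len)
    b[seq_len(min(edge, len))] <- TRUE
    b[max(1L, len - edge + 1L):len] <- TRUE
    b
  })
}

block_around <- function(blocked, chrom, pos, margin) {
  len <- length(blocked[[chrom]])
  for (p in pos) {
    lo <- max(1L, p - margin); hi <- min(len, p + margin)
    blocked[[chrom]][lo:hi] <- TRUE
  }
  blocked
}

#' Generate parental variants and deletion masks
#'
#' Parental SNP/indel differences from the reference at the configured
#' densities (single-sample, homozygous alternate), and merged, sorted
#' deletion-mask intervals covering \code{masked_fraction} of the
#' genome.
#'
#' @param reference a \code{DNAStringSet}.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{variants} (a \code{VariantSet}) and
#'   \code{masks} (a \code{GRanges}).
#' @export
simulate_parental <- function(reference, config = sim_config()) {
  set.seed(config$seed + 1L)
  chars <- genome_chars(reference)
  contigs <- setNames(Biostrings::width(reference), names(reference))

  # deletion masks: exponential-length intervals placed without
  # overlap until the target fraction is covered
  mask_df <- list()
  for (ch in names(contigs)) {
    len <- contigs[[ch]]
    target <- config$masked_fraction * len
    covered <- 0; used <- logical(len)
    guard <- 0L
    while (covered < target && guard < 10000L) {
      guard <- guard + 1L
      w <- max(200L, round(stats::rexp(1, 1 / config$mask_mean_len)))
      s <- sample.int(len - w, 1)
      if (any(used[s:(s + w - 1L)])) next
      used[s:(s + w - 1L)] <- TRUE
      covered <- covered + w
      mask_df[[length(mask_df) + 1L]] <-
        data.frame(chrom = ch, start = s, end = s + w - 1L)
    }
  }
  mask_df <- do.call(rbind, mask_df)
  masks <- GenomicRanges::reduce(GenomicRanges::sort(
    GenomicRanges::GRanges(mask_df$chrom,
                           IRanges::IRanges(mask_df$start,
                                            mask_df$end))))

  # parental variants at the configured densities
  chrom <- character(0); pos <- integer(0)
  ref <- character(0); alt <- character(0)
  pins <- base_probs(config$gc_fraction)
  for (ch in names(contigs)) {
    len <- contigs[[ch]]
    n_snp <- round(config$parental_snp_per_kb * len / 1000)
    n_ind <- round(config$parental_indel_per_kb * len / 1000)
    # unique positions with enough spacing for indel spans
    cand <- sort(sample.int(len - 20L, (n_snp + n_ind) * 2) + 5L)
    cand <- cand[c(TRUE, diff(cand) > 15L)]
    cand <- cand[sample.int(length(cand))]
    fail_if(length(cand) < n_snp + n_ind,
            "contig too small for the requested parental density")
    sp <- cand[seq_len(n_snp)]
    ip <- cand[n_snp + seq_len(n_ind)]
    for (p in sp) {
      b <- chars[[ch]][p]
      chrom <- c(chrom, ch); pos <- c(pos, p); ref <- c(ref, b)
      alt <- c(alt, sample(setdiff(BASES, b), 1))
    }
    for (p in ip) {
      b <- chars[[ch]][p]
      l <- sample.int(8L, 1)
      if (stats::runif(1) < 0.5) {   # deletion
        chrom <- c(chrom, ch); pos <- c(pos, p)
        ref <- c(ref, paste(chars[[ch]][p:(p + l)], collapse = ""))
        alt <- c(alt, b)
      } else {                       # insertion
        chrom <- c(chrom, ch); pos <- c(pos, p)
        ref <- c(ref, b)
        alt <- c(alt, paste(c(b, sample(BASES, l, replace = TRUE,
                                        prob = pins)), collapse = ""))
      }
    }
  }
  ord <- order(chrom, pos)
  v <- variant_set(chrom[ord], pos[ord], ref[ord], alt[ord],
                   qual = rep(500, length(ord)),
                   gt = matrix(2L, length(ord), 1,
                               dimnames = list(NULL, "parent")),
                   dp = matrix(60L, length(ord), 1),
                   samples = "parent")
  list(variants = v, masks = masks)
}

#' Generate a diversity panel with a configurable frequency spectrum
#'
#' Site allele counts follow a truncated neutral law (P(AC = i)
#' proportional to 1/i over 1..2n-1 haploid copies for n diploid
#' lines); genotypes realise each count exactly (hom-alt pairs plus at
#' most one het). Both the rare (AC <= 2) and common (AC >= 3) strata
#' are non-empty at the defaults.
#'
#' @param reference a \code{DNAStringSet}.
#' @param config a \code{\link{sim_config}}.
#' @param avoid optional data frame \code{(chrom, pos)} of positions
#'   to keep clear of.
#' @return a multi-sample \code{VariantSet}.
#' @export
simulate_panel <- function(reference, config = sim_config(),
                           avoid = NULL) {
  set.seed(config$seed + 2L)
  chars <- genome_chars(reference)
  contigs <- setNames(Biostrings::width(reference), names(reference))
  n <- config$panel_n_lines
  n_hap <- 2L * n
  ac_levels <- seq_len(n_hap - 1L)
  ac_probs <- (1 / ac_levels) / sum(1 / ac_levels)
  pins <- base_probs(config$gc_fraction)

  chrom <- character(0); pos <- integer(0)
  ref <- character(0); alt <- character(0)
  gt <- list()
  avoid_key <- if (!is.null(avoid)) paste(avoid$chrom, avoid$pos)
  for (ch in names(contigs)) {
    len <- contigs[[ch]]
    n_snp <- round(config$panel_snp_per_kb * len / 1000)
    n_ind <- round(config$panel_indel_per_kb * len / 1000)
    cand <- sort(sample.int(len - 20L, (n_snp + n_ind) * 2) + 5L)
    cand <- cand[c(TRUE, diff(cand) > 15L)]
    if (!is.null(avoid_key))
      cand <- cand[!(paste(ch, cand) %in% avoid_key)]
    cand <- cand[sample.int(length(cand))]
    fail_if(length(cand) < n_snp + n_ind,
            "contig too small for the requested panel density")
    for (t in seq_len(n_snp + n_ind)) {
      p <- cand[t]
      b <- chars[[ch]][p]
      if (t <= n_snp) {
        r <- b; a <- sample(setdiff(BASES, b), 1)
      } else if (stats::runif(1) < config$panel_insertion_fraction) {
        l <- sample.int(8L, 1)
        r <- b
        a <- paste(c(b, sample(BASES, l, replace = TRUE, prob = pins)),
                   collapse = "")
      } else {
        l <- sample.int(8L, 1)
        r <- paste(chars[[ch]][p:(p + l)], collapse = "")
        a <- b
      }
      ac <- sample(ac_levels, 1, prob = ac_probs)
      dos <- integer(n)
      lines_idx <- sample.int(n, ceiling(ac / 2))
      dos[lines_idx] <- 2L
      if (ac %% 2L == 1L) dos[lines_idx[1]] <- 1L
      chrom <- c(chrom, ch); pos <- c(pos, p)
      ref <- c(ref, r); alt <- c(alt, a)
      gt[[length(gt) + 1L]] <- dos
    }
  }
  ord <- order(chrom, pos)
  gt <- do.call(rbind, gt)[ord, , drop = FALSE]
  samples <- sprintf("panel%02d", seq_len(n))
  colnames(gt) <- samples
  variant_set(chrom[ord], pos[ord], ref[ord], alt[ord],
              qual = rep(500, length(ord)), gt = gt,
              dp = matrix(30L, length(ord), n), samples = samples)
}

## --- FN cohort ------------------------------------------------------

# stratified site index for SNP planting: per contig and canonical
# class-reference base, CpG-context and non-CpG candidate positions
build_site_index <- function(chars) {
  lapply(chars, function(v) {
    n <- length(v)
    nxt <- c(v[-1], "N"); prv <- c("N", v[-n])
    cpos <- which(v == "C"); gpos <- which(v == "G")
    apos <- which(v == "A"); tpos <- which(v == "T")
    list(
      C = list(cpg = c(cpos[nxt[cpos] == "G"], gpos[prv[gpos] == "C"]),
               noncpg = c(cpos[nxt[cpos] != "G"],
                          gpos[prv[gpos] != "C"])),
      A = list(cpg = integer(0), noncpg = c(apos, tpos))
    )
  })
}

draw_unblocked <- function(cands, blocked_v, n_try = 200L) {
  for (t in seq_len(n_try)) {
    p <- cands[sample.int(length(cands), 1L)]
    if (!blocked_v[p]) return(p)
  }
  NA_integer_
}

#' Generate the treatment cohort with planted truth
#'
#' Plants per-line Poisson numbers of homozygous-alternate de novo
#' SNPs and indels at unmasked, non-parental, non-panel, mutually
#' non-overlapping sites; SNP classes follow the configured six-class
#' law with a CpG-conditional preference for C>T*, indel signed
#' lengths the configured deletion-skewed law with an A/T bias in
#' 1-bp events. Enabled noise layers add spurious heterozygous calls,
#' low-coverage calls, and heterogeneity variants shared by non-sibling
#' lines; every record is tagged in the truth table.
#'
#' @param reference a \code{DNAStringSet}.
#' @param parental output of \code{\link{simulate_parental}}.
#' @param panel optional panel \code{VariantSet} whose positions are
#'   kept clear.
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{variants} (multi-sample \code{VariantSet}
#'   over the treatment lines), \code{meta} (line metadata data frame)
#'   and \code{truth} (one row per record: position, alleles, line,
#'   class, collapsed class, signed length, CpG flag and an
#'   \code{origin} tag, \code{"planted"} or the noise layer name).
#' @export
simulate_fn_cohort <- function(reference, parental, panel = NULL,
                               config = sim_config()) {
  set.seed(config$seed + 3L)
  chars <- genome_chars(reference)
  contigs <- setNames(Biostrings::width(reference), names(reference))
  nl <- config$fn_n_lines
  lines <- sprintf("line%02d", seq_len(nl))

  # metadata: dosage and selfing-generation mix typical of an
  # irradiated selfing cohort, with two sibling families of three
  meta <- data.frame(sample = lines,
                     dosage_gy = sample(c(8, 16, 32), nl,
                                        replace = TRUE,
                                        prob = c(1, 16, 10) / 27),
                     selfing_generations = sample(3:8, nl,
                                                  replace = TRUE,
                                                  prob = c(1, 5, 11, 4,
                                                           4, 3) / 28),
                     family = "", stringsAsFactors = FALSE)
  if (nl >= 7) {
    meta$family[2:4] <- "fam1"
    meta$family[5:7] <- "fam2"
  }

  blocked <- new_blocked(contigs)
  for (ch in unique(parental$variants$chrom))
    blocked <- block_around(blocked, ch,
                            parental$variants$pos[
                              parental$variants$chrom == ch],
                            config$site_margin)
  if (length(parental$masks) > 0) {
    mdf <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(parental$masks)),
      start = GenomicRanges::start(parental$masks),
      end = GenomicRanges::end(parental$masks))
    for (i in seq_len(nrow(mdf))) {
      lo <- max(1L, mdf$start[i] - config$site_margin)
      hi <- min(contigs[[mdf$chrom[i]]], mdf$end[i] + config$site_margin)
      blocked[[mdf$chrom[i]]][lo:hi] <- TRUE
    }
  }
  if (!is.null(panel))
    for (ch in unique(panel$chrom))
      blocked <- block_around(blocked, ch, panel$pos[panel$chrom == ch],
                              config$site_margin)

  sidx <- build_site_index(chars)
  all_pos <- lapply(chars, seq_along)
  base_pos <- lapply(chars, function(v) split(seq_along(v), v))
  canon_ref <- substr(COLLAPSED_CLASSES, 1, 1)
  canon_alt <- substr(COLLAPSED_CLASSES, 3, 3)
  names(canon_ref) <- names(canon_alt) <- COLLAPSED_CLASSES
  class_names <- names(config$class_probs)

  rec <- list()   # accumulated records
  n_resampled <- 0L
  add_record <- function(ch, p, r, a, line, cls, ccls, sl, cpg, origin,
                         dosage = 2L, depth = NULL) {
    rec[[length(rec) + 1L]] <<- list(chrom = ch, pos = p, ref = r,
                                     alt = a, line = line, class = cls,
                                     collapsed_class = ccls,
                                     signed_length = sl, cpg = cpg,
                                     origin = origin, dosage = dosage,
                                     depth = depth)
    blocked <<- block_around(blocked, ch, p, config$site_margin)
  }

  pick_contig <- function() sample(names(contigs), 1,
                                   prob = contigs / sum(contigs))

  plant_snp <- function(line, origin = "planted",
                        dosage = 2L, depth = NULL) {
    ccls <- sample(class_names, 1, prob = config$class_probs)
    cr <- canon_ref[[ccls]]; ca <- canon_alt[[ccls]]
    repeat {
      ch <- pick_contig()
      str <- sidx[[ch]][[cr]]
      # CpG-conditional boost applies to the C-reference classes;
      # only C>T* gets a boost above 1 by default
      boost <- if (ccls == "C>T*") config$cpg_boost else 1
      n_c <- length(str$cpg); n_n <- length(str$noncpg)
      use_cpg <- n_c > 0 &&
        stats::runif(1) < boost * n_c / (boost * n_c + n_n)
      p <- draw_unblocked(if (use_cpg) str$cpg else str$noncpg,
                          blocked[[ch]])
      if (is.na(p)) { n_resampled <<- n_resampled + 1L; next }
      b <- chars[[ch]][p]
      if (b == cr) { r <- cr; a <- ca }
      else { r <- complement_chr(cr); a <- complement_chr(ca) }
      nxt <- chars[[ch]][p + 1L]; prv <- chars[[ch]][p - 1L]
      cpg <- (b == "C" && nxt == "G") || (b == "G" && prv == "C")
      add_record(ch, p, r, a, line, "SNP", ccls, 0L, cpg, origin,
                 dosage, depth)
      return(invisible(NULL))
    }
  }

  pins <- base_probs(config$gc_fraction)
  plant_indel <- function(line, origin = "planted",
                          dosage = 2L, depth = NULL) {
    is_del <- stats::runif(1) < config$deletion_fraction
    l <- min(1L + stats::rgeom(1, config$indel_geom_p),
             config$max_indel)
    repeat {
      ch <- pick_contig()
      if (l == 1L) {
        at <- stats::runif(1) < config$at_bias_1bp
        b <- if (at) sample(c("A", "T"), 1) else sample(c("C", "G"), 1)
        if (is_del) {
          # need a site whose following base is b
          cands <- base_pos[[ch]][[b]] - 1L
          if (cands[1] < 1L) cands <- cands[-1]
          p <- draw_unblocked(cands, blocked[[ch]])
          if (is.na(p)) { n_resampled <<- n_resampled + 1L; next }
          r <- paste0(chars[[ch]][p], b); a <- chars[[ch]][p]
        } else {
          p <- draw_unblocked(all_pos[[ch]], blocked[[ch]])
          if (is.na(p)) { n_resampled <<- n_resampled + 1L; next }
          r <- chars[[ch]][p]; a <- paste0(r, b)
        }
      } else {
        p <- draw_unblocked(all_pos[[ch]], blocked[[ch]])
        if (!is.na(p) && p + l + 1L > length(chars[[ch]]))
          p <- NA_integer_
        if (is.na(p)) { n_resampled <<- n_resampled + 1L; next }
        if (is_del) {
          r <- paste(chars[[ch]][p:(p + l)], collapse = "")
          a <- chars[[ch]][p]
        } else {
          r <- chars[[ch]][p]
          a <- paste(c(r, sample(BASES, l, replace = TRUE,
                                 prob = pins)), collapse = "")
        }
      }
      add_record(ch, p, r, a, line,
                 if (is_del) "deletion" else "insertion", NA_character_,
                 if (is_del) -l else l, NA, origin, dosage, depth)
      return(invisible(NULL))
    }
  }

  for (li in seq_len(nl)) {
    for (s in seq_len(stats::rpois(1, config$lambda_snp)))
      plant_snp(lines[li])
    for (s in seq_len(stats::rpois(1, config$lambda_indel)))
      plant_indel(lines[li])
  }
  n_planted <- length(rec)

  # noise layers
  if (config$het_rate > 0) {
    for (s in seq_len(round(config$het_rate * n_planted)))
      plant_snp(sample(lines, 1), origin = "het_call", dosage = 1L)
  }
  if (config$low_depth_rate > 0) {
    for (s in seq_len(round(config$low_depth_rate * n_planted)))
      plant_snp(sample(lines, 1), origin = "low_depth",
                depth = sample(0:4, 1))
  }
  if (config$n_heterogeneity > 0) {
    non_sib <- which(meta$family == "")
    for (s in seq_len(config$n_heterogeneity)) {
      carriers <- sample(non_sib, sample(2:4, 1))
      plant_snp(lines[carriers[1]], origin = "heterogeneity")
      # expand the record to all carriers
      rec[[length(rec)]]$line <- paste(lines[carriers],
                                       collapse = ",")
    }
  }

  truth <- do.call(rbind, lapply(rec, function(r)
    data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref, alt = r$alt,
               line = r$line, class = r$class,
               collapsed_class = r$collapsed_class,
               signed_length = r$signed_length, cpg = r$cpg,
               origin = r$origin, stringsAsFactors = FALSE)))

  # genotype matrices
  nv <- length(rec)
  gt <- matrix(0L, nv, nl, dimnames = list(NULL, lines))
  dp <- matrix(stats::rpois(nv * nl, config$mean_depth), nv, nl,
               dimnames = list(NULL, lines))
  dp[dp < 5L] <- 5L
  for (i in seq_len(nv)) {
    carriers <- strsplit(rec[[i]]$line, ",", fixed = TRUE)[[1]]
    ci <- match(carriers, lines)
    gt[i, ci] <- rec[[i]]$dosage
    if (!is.null(rec[[i]]$depth)) dp[i, ci] <- rec[[i]]$depth
  }
  qual <- round(stats::runif(nv, 100, 999))

  ord <- order(truth$chrom, truth$pos)
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  v <- variant_set(truth$chrom, truth$pos, truth$ref, truth$alt,
                   qual = qual[ord],
                   gt = gt[ord, , drop = FALSE],
                   dp = dp[ord, , drop = FALSE], samples = lines)
  list(variants = v, meta = meta, truth = truth,
       n_resampled = n_resampled)
}

#' Generate gene models (and patch the reference to match)
#'
#' Places non-overlapping multi-exon genes on both strands with a CDS
#' whose length is divisible by three, a valid start and stop codon,
#' no internal stop, derived UTR exons, and introns of at least 20 bp.
#' Because the reference is random, the coding sequence is written
#' into the returned (patched) reference so that the models and the
#' sequence agree.
#'
#' @param reference a \code{DNAStringSet}.
#' @param n_genes number of genes to place.
#' @param seed RNG seed.
#' @return list with \code{models} (a \code{\link{gene_models}}
#'   object) and \code{reference} (the patched \code{DNAStringSet}).
#' @export
simulate_gene_models <- function(reference, n_genes = 8, seed = 1) {
  set.seed(seed)
  chars <- genome_chars(reference)
  contigs <- setNames(Biostrings::width(reference), names(reference))
  if (n_genes == 0)
    return(list(models = gene_models(
      data.frame(tx_id = character(0), gene_id = character(0),
                 chrom = character(0), strand = character(0),
                 start = integer(0), end = integer(0)),
      data.frame(tx_id = character(0), start = integer(0),
                 end = integer(0)),
      data.frame(tx_id = character(0), start = integer(0),
                 end = integer(0), phase = integer(0))),
      reference = reference))

  sense_codons <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))
  tx_rows <- list(); ex_rows <- list(); cds_rows <- list()
  next_start <- lapply(contigs, function(x) 20000L)

  for (g in seq_len(n_genes)) {
    ch <- names(contigs)[(g - 1L) %% length(contigs) + 1L]
    strand <- if (g %% 2L == 0L) "-" else "+"
    n_aa <- sample(80:250, 1)
    cds_len <- 3L * (n_aa + 2L)       # incl. start and stop codons
    n_ex <- sample(2:3, 1)
    # split the CDS into exon chunks of >= 30 bases
    cuts <- sort(sample(seq(30L, cds_len - 30L, by = 3L), n_ex - 1L))
    chunk_len <- diff(c(0L, cuts, cds_len))
    intron_len <- sample(50:400, n_ex - 1L, replace = TRUE)
    utr5 <- sample(50:200, 1); utr3 <- sample(50:200, 1)

    s <- next_start[[ch]]
    fail_if(s + cds_len + sum(intron_len) + utr5 + utr3 + 20000L >
              contigs[[ch]], "genome too small for %d genes", n_genes)
    # genomic layout left-to-right; biological orientation by strand
    left_utr <- if (strand == "+") utr5 else utr3
    right_utr <- if (strand == "+") utr3 else utr5
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    cd_start <- integer(n_ex); cd_end <- integer(n_ex)
    cur <- s
    for (j in seq_len(n_ex)) {
      cl <- if (strand == "+") chunk_len[j] else rev(chunk_len)[j]
      exs <- cur
      cds_s <- if (j == 1L) exs + left_utr else exs
      cds_e <- cds_s + cl - 1L
      exe <- if (j == n_ex) cds_e + right_utr else cds_e
      ex_start[j] <- exs; ex_end[j] <- exe
      cd_start[j] <- cds_s; cd_end[j] <- cds_e
      cur <- exe + 1L + if (j < n_ex) intron_len[j] else 0L
    }
    gene_end <- ex_end[n_ex]
    next_start[[ch]] <- gene_end + 20000L

    # coding sequence: ATG + sense codons + stop
    cds_seq <- paste0("ATG",
                      paste(sample(sense_codons, n_aa, replace = TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1))
    # write into the genome: chunks in coding order map to genomic
    # intervals left-to-right (+) or right-to-left with revcomp (-)
    offs <- cumsum(c(0L, chunk_len))
    for (j in seq_len(n_ex)) {
      piece <- substr(cds_seq, offs[j] + 1L, offs[j + 1L])
      if (strand == "+") {
        tgt <- cd_start[j]:cd_end[j]
        chars[[ch]][tgt] <- strsplit(piece, "", fixed = TRUE)[[1]]
      } else {
        jj <- n_ex - j + 1L           # genomic interval, right to left
        tgt <- cd_start[jj]:cd_end[jj]
        chars[[ch]][tgt] <- strsplit(revcomp_chr(piece), "",
                                     fixed = TRUE)[[1]]
      }
    }

    id <- sprintf("gene%02d", g); txid <- paste0(id, ".t1")
    tx_rows[[g]] <- data.frame(tx_id = txid, gene_id = id, chrom = ch,
                               strand = strand, start = s,
                               end = gene_end, stringsAsFactors = FALSE)
    ex_rows[[g]] <- data.frame(tx_id = txid, start = ex_start,
                               end = ex_end, stringsAsFactors = FALSE)
    # CDS phases in coding order
    cum <- cumsum(c(0L, chunk_len))[seq_len(n_ex)]
    phase <- (3L - (cum %% 3L)) %% 3L
    if (strand == "+") {
      cds_rows[[g]] <- data.frame(tx_id = txid, start = cd_start,
                                  end = cd_end, phase = phase,
                                  stringsAsFactors = FALSE)
    } else {
      cds_rows[[g]] <- data.frame(tx_id = txid, start = cd_start,
                                  end = cd_end, phase = rev(phase),
                                  stringsAsFactors = FALSE)
    }
  }
  gm <- gene_models(do.call(rbind, tx_rows), do.call(rbind, ex_rows),
                    do.call(rbind, cds_rows))
  list(models = gm, reference = chars_to_dss(chars))
}

#' Simulate a complete synthetic study
#'
#' Orchestrates reference, gene models (patching the reference),
#' parental variants and masks, the diversity panel, and the treatment
#' cohort; optionally writes the full file bundle (FASTA, VCFs, BED,
#' GFF3, metadata and truth TSVs) to a directory. Byte-identical
#' outputs under a fixed seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir optional output directory (created if needed).
#' @param n_genes genes to place (default 8).
#' @return list with elements \code{reference, gene_models, parental,
#'   masks, panel, fn} (cohort list), \code{config}, and \code{paths}
#'   when files were written.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL,
                           n_genes = 8) {
  ref0 <- simulate_reference(config)
  gmres <- simulate_gene_models(ref0, n_genes = n_genes,
                                seed = config$seed + 10L)
  reference <- gmres$reference
  par <- simulate_parental(reference, config)
  panel <- simulate_panel(reference, config,
                          avoid = data.frame(
                            chrom = par$variants$chrom,
                            pos = par$variants$pos))
  fn <- simulate_fn_cohort(reference, par, panel, config)
  out <- list(reference = reference, gene_models = gmres$models,
              parental = par$variants, masks = par$masks,
              panel = panel, fn = fn, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      reference = file.path(out_dir, "reference.fa"),
      parental = file.path(out_dir, "parental.vcf"),
      mask = file.path(out_dir, "mask.bed"),
      panel = file.path(out_dir, "panel.vcf"),
      fn = file.path(out_dir, "fn_lines.vcf"),
      meta = file.path(out_dir, "meta.tsv"),
      genes = file.path(out_dir, "genes.gff3"),
      truth = file.path(out_dir, "truth.tsv"))
    write_reference(reference, paths$reference)
    write_vcf(par$variants, paths$parental, reference)
    write_mask_bed(par$masks, paths$mask)
    write_vcf(panel, paths$panel, reference)
    write_vcf(fn$variants, paths$fn, reference)
    write_line_meta(fn$meta, paths$meta)
    write_gene_models(gmres$models, paths$genes)
    write.table(fn$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- paths
  }
  out
}
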