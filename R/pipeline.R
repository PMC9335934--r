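# Orchestration: run the full analysis over a simulated or on-disk
# study and aggregate every stage's output into one report, plus a
# summary-only entry point for published count tables (so the worked
# examples run without any VCF).

#' Bundled example: per-line counts from a published cohort
#'
#' Per-line SNP and indel totals, selfing generations and radiation
#' dosage for 27 fast-neutron irradiated soybean lines (two sibling
#' families marked), as reported for a published mutagenesis cohort.
#'
#' @return data frame with columns \code{sample, selfing_generations,
#'   dosage_gy, mean_depth, n_indel, n_snp, family}.
#' @export
fn_example_line_counts <- function() {
  read.table(system.file("extdata", "fn_line_counts.tsv",
                         package = "fnmut"),
             header = TRUE, sep = "\t", quote = "",
             colClasses = c("character", "numeric", "integer",
                            "integer", "integer", "integer",
                            "character"))
}

#' Bundled example: transcript consequence counts
#'
#' Counts of affected transcripts per consequence class for the same
#' published cohort (column \code{fn27}) and for the common and rare
#' strata of standing variation.
#'
#' @return data frame with columns \code{consequence, fn27, common,
#'   rare}.
#' @export
fn_example_consequence_counts <- function() {
  read.table(system.file("extdata", "consequence_counts.tsv",
                         package = "fnmut"),
             header = TRUE, sep = "\t", quote = "",
             stringsAsFactors = FALSE)
}

#' Summary-only analysis of published count tables
#'
#' Computes the per-line summary and SNP-indel association statistics
#' from a per-line counts table, and frameshift-of-coding percentages
#' from a consequence count table, without touching any VCF.
#'
#' @param line_counts data frame with \code{sample, n_snp, n_indel}
#'   and, for the ANOVA, \code{dosage_gy} and
#'   \code{selfing_generations} (default: the bundled example).
#' @param consequence_counts data frame with \code{consequence} and
#'   one count column per cohort (default: the bundled example).
#' @return list with \code{per_line} (a
#'   \code{\link{per_line_summary}}), \code{association} (an
#'   \code{association_result}) and \code{frameshift_pct} (named
#'   vector, one entry per cohort column).
#' @export
summarize_counts <- function(line_counts = fn_example_line_counts(),
                             consequence_counts =
                               fn_example_consequence_counts()) {
  pls <- per_line_summary(line_counts)
  assoc <- snp_indel_association(line_counts)
  cohorts <- setdiff(names(consequence_counts), "consequence")
  fs <- vapply(cohorts, function(co)
    frameshift_fraction_of_coding(
      setNames(consequence_counts[[co]],
               consequence_counts$consequence)),
    numeric(1))
  list(per_line = pls, association = assoc, frameshift_pct = fs)
}

#' Run the full analysis pipeline
#'
#' Executes the de novo filter, spectrum, context, consequence and
#' population-statistics stages over a study (simulated in memory via
#' \code{\link{simulate_study}}, or read from files) and aggregates
#' the results. Optionally writes per-stage TSVs and a JSON summary.
#'
#' @param study a list as returned by \code{\link{simulate_study}}, or
#'   a list of file paths with elements \code{reference, parental,
#'   mask, panel, fn, meta, genes}.
#' @param out_dir optional output directory for TSVs and
#'   \code{summary.json}.
#' @param filter_config a \code{\link{filter_config}}.
#' @param context_config a \code{\link{context_config}}; its seed
#'   defaults to the study seed when available.
#' @param rate_model a \code{\link{mutation_rate_model}}; its genome
#'   length defaults to the study genome size.
#' @return an \code{fnmut_report} list with per-stage results and a
#'   JSON-ready \code{summary}.
#' @export
run_pipeline <- function(study, out_dir = NULL,
                         filter_config = fnmut::filter_config(),
                         context_config = NULL,
                         rate_model = NULL) {
  if (!is.null(study$paths) || is.character(study$reference)) {
    # file-based inputs
    p <- study$paths %||% study
    reference <- read_reference(p$reference)
    parental <- read_variants(p$parental, reference)
    masks <- read_mask_bed(p$mask)
    panel <- read_variants(p$panel, reference)
    fn_variants <- read_variants(p$fn, reference)
    meta <- read_line_meta(p$meta)
    gm <- read_gene_models(p$genes)
    seed <- study$config$seed %||% 1L
  } else {
    reference <- study$reference
    parental <- study$parental
    masks <- study$masks
    panel <- study$panel
    fn_variants <- study$fn$variants
    meta <- study$fn$meta
    gm <- study$gene_models
    seed <- study$config$seed
  }
  L <- sum(Biostrings::width(reference))
  if (is.null(context_config))
    context_config <- fnmut::context_config(seed = seed)
  if (is.null(rate_model))
    rate_model <- mutation_rate_model(L = L)

  # stage 1: de novo isolation
  dn <- isolate_de_novo(fn_variants, parental, panel, masks, meta,
                        filter_config)
  # stage 2: spectra (FN + rare/common standing)
  strata <- partition_by_frequency(panel)
  pick_snps <- function(v) {
    cls <- classify_variant(v$ref, v$alt)
    v[cls$label == "SNP"]
  }
  fn_snps <- dn$variants[dn$table$class == "SNP"]
  spectra <- list(
    fn = spectrum_table(fn_snps, "FN"),
    rare = spectrum_table(pick_snps(strata$rare), "rare standing"),
    common = spectrum_table(pick_snps(strata$common),
                            "common standing"))
  pls <- per_line_summary(dn)
  assoc <- snp_indel_association(dn$per_line)

  # stage 3: context profile for the dominant class
  obs_win <- extract_flanks(fn_snps, reference, context_config)
  null_win <- sample_null_windows(fn_snps, reference, context_config)
  re_ct <- relative_entropy_profile(obs_win, null_win, "C>T*")

  # stage 4: indels and consequences
  fn_indels <- dn$variants[dn$table$class %in% c("insertion",
                                                 "deletion")]
  indel_spec <- list(
    fn = indel_length_spectrum(fn_indels, "FN"),
    rare = indel_length_spectrum(pick_indels(strata$rare),
                                 "rare standing"),
    common = indel_length_spectrum(pick_indels(strata$common),
                                   "common standing"))
  cons <- classify_consequence(dn$variants, gm, reference)
  cons_sum <- consequence_summary(cons, "FN")
  fs_pct <- tryCatch(frameshift_fraction_of_coding(cons_sum),
                     error = function(e) NA_real_)

  # stage 5: diversity and expectations
  snp_singletons <- rep(1L, length(fn_snps))
  div <- if (length(fn_snps) > 0)
    theta_pi(snp_singletons, n = nrow(meta), L = L)
  else list(theta_pi = 0, n = nrow(meta), S = 0L, L = L)
  expect <- data.frame(
    sample = dn$per_line$sample,
    observed_snp = dn$per_line$n_snp,
    expected_snp = expected_spontaneous_count(
      rate_model, "snp", dn$per_line$selfing_generations),
    observed_indel = dn$per_line$n_indel,
    expected_indel = expected_spontaneous_count(
      rate_model, "indel", dn$per_line$selfing_generations))

  summary <- list(
    seed = seed,
    n_lines = nrow(meta),
    n_de_novo = nrow(dn$table),
    n_de_novo_snp = sum(dn$table$class == "SNP"),
    n_de_novo_indel = sum(dn$table$class != "SNP"),
    filter_counts = as.list(dn$filter_counts),
    per_line_mean_total = pls$cohort["total", "mean"],
    per_line_sd_total = pls$cohort["total", "sd"],
    r_squared = assoc$r_squared,
    paired_t_p = assoc$p_value,
    spectrum_fractions = lapply(spectra, function(s)
      setNames(as.list(s$fraction), s$class)),
    ts_tv = lapply(spectra, attr, "ts_tv"),
    re_profile_ct = as.list(re_ct$re_bits),
    insertion_fraction = lapply(indel_spec, attr,
                                "insertion_fraction"),
    frameshift_pct_of_coding = fs_pct,
    theta_pi = div$theta_pi,
    het = observed_heterozygosity(fn_variants)$het)

  report <- structure(list(denovo = dn, spectra = spectra,
                           per_line = pls, association = assoc,
                           re_profile = re_ct,
                           indel_spectra = indel_spec,
                           consequences = cons,
                           consequence_summary = cons_sum,
                           diversity = div, expectations = expect,
                           summary = summary),
                      class = "fnmut_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) write.table(df, file.path(out_dir, f),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
    wt(dn$table, "de_novo_variants.tsv")
    wt(dn$per_line, "per_line_counts.tsv")
    for (nm in names(spectra))
      wt(as.data.frame(spectra[[nm]]), sprintf("spectrum_%s.tsv", nm))
    wt(data.frame(offset = re_ct$offsets, re_bits = re_ct$re_bits,
                  re_ct$contrib), "re_profile_ct.tsv")
    for (nm in names(indel_spec))
      wt(as.data.frame(indel_spec[[nm]]),
         sprintf("indel_lengths_%s.tsv", nm))
    wt(cons_sum, "consequence_summary.tsv")
    wt(expect, "expected_vs_observed.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

pick_indels <- function(v) {
  cls <- classify_variant(v$ref, v$alt)
  v[cls$label %in% c("insertion", "deletion")]
}

#' @export
print.fnmut_report <- function(x, ...) {
  s <- x$summary
  cat("fnmut pipeline report\n")
  cat(sprintf("  de novo variants: %d (%d SNP, %d indel) across %d lines\n",
              s$n_de_novo, s$n_de_novo_snp, s$n_de_novo_indel,
              s$n_lines))
  cat(sprintf("  mean per-line total: %.1f (SD %.1f); r^2(SNP,indel) = %.3f\n",
              s$per_line_mean_total, s$per_line_sd_total, s$r_squared))
  cat(sprintf("  FN C>T* fraction: %.3f; FN insertion fraction: %.3f\n",
              s$spectrum_fractions$fn[["C>T*"]],
              s$insertion_fraction$fn))
  cat(sprintf("  frameshift %% of coding: %.1f; theta_pi = %.3g\n",
              s$frameshift_pct_of_coding, s$theta_pi))
  invisible(x)
}
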