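# Strand-collapsed mutational spectrum. Sequencing cannot identify the
# strand of origin of a substitution, so the 12 ordered base changes
# are pooled into 6 classes, each combining a change and its reverse
# complement; the canonical representative has reference base A or C
# (e.g. C>T* = C>T plus G>A).

#' Strand-collapsed mutation class labels, in display order
#' @export
COLLAPSED_CLASSES <- c("C>T*", "A>G*", "C>A*", "C>G*", "A>T*", "A>C*")

TRANSITION_CLASSES <- c("C>T*", "A>G*")

#' Collapse a base substitution to its strand-collapsed class
#'
#' @param ref_base,alt_base single reference/alternate bases
#'   (vectorized), each in A/C/G/T, unequal pairwise.
#' @return character vector of class labels, e.g. \code{"C>T*"}.
#' @examples
#' collapse_class("G", "A")  # "C>T*"
#' @export
collapse_class <- function(ref_base, alt_base) {
  fail_if(!all(ref_base %in% BASES) || !all(alt_base %in% BASES),
          "bases must be A, C, G or T")
  fail_if(any(ref_base == alt_base), "ref and alt base are identical")
  flip <- ref_base %in% c("G", "T")
  r <- ifelse(flip, complement_chr(ref_base), ref_base)
  a <- ifelse(flip, complement_chr(alt_base), alt_base)
  paste0(r, ">", a, "*")
}

#' Spectrum table from per-class counts
#'
#' @param counts named numeric vector over the six collapsed classes
#'   (missing classes are taken as zero).
#' @param cohort_label label for the cohort (e.g. \code{"FN"}).
#' @return a \code{spectrum_table} data frame (class, count, fraction)
#'   with attributes \code{ts}, \code{tv}, \code{ts_tv} and
#'   \code{cohort}; Ts/Tv is \code{Inf} (flagged) when there are no
#'   transversions.
#' @export
spectrum_from_counts <- function(counts, cohort_label = "cohort") {
  fail_if(sum(counts) == 0, "empty spectrum: no substitutions")
  bad <- setdiff(names(counts), COLLAPSED_CLASSES)
  fail_if(length(bad) > 0, "unknown class label: %s", bad[1])
  full <- setNames(numeric(length(COLLAPSED_CLASSES)), COLLAPSED_CLASSES)
  full[names(counts)] <- counts
  tab <- data.frame(class = COLLAPSED_CLASSES, count = as.numeric(full),
                    fraction = as.numeric(full) / sum(full),
                    stringsAsFactors = FALSE)
  ts <- sum(full[TRANSITION_CLASSES])
  tv <- sum(full[setdiff(COLLAPSED_CLASSES, TRANSITION_CLASSES)])
  structure(tab, class = c("spectrum_table", "data.frame"),
            ts = ts, tv = tv,
            ts_tv = if (tv > 0) ts / tv else Inf,
            ts_tv_degenerate = tv == 0,
            cohort = cohort_label)
}

#' Strand-collapsed mutational spectrum of a SNP set
#'
#' @param snvs a \code{\link{variant_set}} containing only SNP-class
#'   variants, or a data frame with \code{ref}/\code{alt} columns of
#'   single bases.
#' @param cohort_label cohort label carried into the output.
#' @return see \code{\link{spectrum_from_counts}}.
#' @export
spectrum_table <- function(snvs, cohort_label = "cohort") {
  if (is(snvs, "VariantSet")) snvs <- as_variant_frame(snvs)
  fail_if(nrow(snvs) == 0, "empty spectrum: no substitutions")
  fail_if(!all(nchar(snvs$ref) == 1 & nchar(snvs$alt) == 1),
          "spectrum_table expects SNP-class variants only")
  cls <- collapse_class(snvs$ref, snvs$alt)
  spectrum_from_counts(table(cls), cohort_label)
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat(sprintf("Mutational spectrum (%s): %d substitutions\n",
              attr(x, "cohort"), sum(x$count)))
  df <- as.data.frame(x)
  df$fraction <- sprintf("%.4f", df$fraction)
  print(df, row.names = FALSE)
  cat(sprintf("Ts/Tv = %s (Ts %d, Tv %d)\n",
              if (attr(x, "ts_tv_degenerate")) "Inf (no transversions)"
              else sprintf("%.3f", attr(x, "ts_tv")),
              attr(x, "ts"), attr(x, "tv")))
  invisible(x)
}

#' Bar plot of one or more spectra
#' @param x a \code{spectrum_table}.
#' @param ... further spectra to draw alongside.
#' @export
plot.spectrum_table <- function(x, ...) {
  others <- list(...)
  others <- others[vapply(others, inherits, TRUE, "spectrum_table")]
  mats <- c(list(x), others)
  m <- do.call(rbind, lapply(mats, function(s) s$fraction))
  rownames(m) <- vapply(mats, attr, "", "cohort")
  colnames(m) <- x$class
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "fraction of substitutions",
                    xlab = "strand-collapsed class")
  invisible(x)
}

#' Per-line variant counts with cohort mean and SD
#'
#' @param denovo a \code{DeNovoSet} from \code{\link{isolate_de_novo}},
#'   or a data frame with columns \code{sample, n_snp, n_indel} (and
#'   optionally \code{n_total}).
#' @return a \code{per_line_summary} list: \code{per_line} (the table)
#'   and \code{cohort} (mean and sample SD, n-1 denominator, for SNPs,
#'   indels and totals; SD is \code{NA} and flagged when n = 1).
#' @export
per_line_summary <- function(denovo) {
  pl <- if (inherits(denovo, "DeNovoSet")) denovo$per_line else denovo
  fail_if(!all(c("sample", "n_snp", "n_indel") %in% names(pl)),
          "need columns sample, n_snp, n_indel")
  if (is.null(pl$n_total)) pl$n_total <- pl$n_snp + pl$n_indel
  n <- nrow(pl)
  stat <- function(v) c(mean = mean(v),
                        sd = if (n > 1) sd(v) else NA_real_)
  cohort <- rbind(snp = stat(pl$n_snp), indel = stat(pl$n_indel),
                  total = stat(pl$n_total))
  structure(list(per_line = pl,
                 cohort = as.data.frame(cohort),
                 n_lines = n, sd_defined = n > 1),
            class = "per_line_summary")
}

#' @export
print.per_line_summary <- function(x, ...) {
  cat(sprintf("Per-line summary over %d lines\n", x$n_lines))
  print(round(x$cohort, 2))
  if (!x$sd_defined) cat("  (SD undefined with a single line)\n")
  invisible(x)
}

#' Association between per-line SNP and indel counts
#'
#' Computes the squared Pearson correlation of per-line SNP and indel
#' counts, a paired two-sided t-test on the same pairs, and a two-way
#' ANOVA (type II sums of squares) of total counts on radiation dosage
#' and selfing generations, both treated as categorical.
#'
#' @param per_line data frame with columns \code{n_snp, n_indel} and,
#'   for the ANOVA, \code{dosage_gy} and \code{selfing_generations}
#'   (ANOVA is skipped with a note when these are absent or constant).
#' @return an \code{association_result} list: \code{r_squared},
#'   \code{pearson_r}, \code{t_statistic}, \code{p_value},
#'   \code{anova} (data frame or \code{NULL}), and a
#'   \code{degenerate} flag set when either count column is constant.
#' @export
snp_indel_association <- function(per_line) {
  fail_if(nrow(per_line) < 3, "need at least 3 lines")
  snp <- per_line$n_snp; ind <- per_line$n_indel
  degenerate <- sd(snp) == 0 || sd(ind) == 0
  if (degenerate) {
    r <- NA_real_; r2 <- if (identical(snp, ind)) 1 else NA_real_
  } else {
    r <- cor(snp, ind); r2 <- r^2
  }
  tt <- tryCatch(t.test(snp, ind, paired = TRUE),
                 error = function(e) NULL)
  an <- NULL
  if (all(c("dosage_gy", "selfing_generations") %in% names(per_line))) {
    d <- factor(per_line$dosage_gy)
    g <- factor(per_line$selfing_generations)
    if (nlevels(d) > 1 && nlevels(g) > 1) {
      tot <- snp + ind
      fit <- lm(tot ~ d + g)
      a2 <- car::Anova(fit, type = 2)
      an <- data.frame(factor = c("dosage_gy", "selfing_generations",
                                  "residuals"),
                       sum_sq = a2[["Sum Sq"]],
                       df = a2[["Df"]],
                       F = a2[["F value"]],
                       p = a2[["Pr(>F)"]],
                       stringsAsFactors = FALSE)
    }
  }
  structure(list(r_squared = r2, pearson_r = r,
                 t_statistic = if (!is.null(tt)) unname(tt$statistic)
                               else NA_real_,
                 p_value = if (!is.null(tt)) tt$p.value else NA_real_,
                 anova = an, degenerate = degenerate,
                 n = nrow(per_line)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("SNP-indel association over %d lines\n", x$n))
  cat(sprintf("  r^2 = %.3f%s\n", x$r_squared,
              if (x$degenerate) " (degenerate: constant column)" else ""))
  cat(sprintf("  paired t = %.3f, two-sided p = %.3g\n",
              x$t_statistic, x$p_value))
  if (!is.null(x$anova)) {
    cat("  two-way ANOVA (type II) of total counts:\n")
    print(x$anova, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
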