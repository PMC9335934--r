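# Diversity statistics and spontaneous-mutation expectations.
# theta_pi uses the unbiased per-site heterozygosity with the
# n/(n-1) correction, averaged over all L sites (monomorphic sites
# contribute zero), appropriate for a haploid sample of inbred lines.

#' Spontaneous mutation-rate model
#'
#' Per-generation single-nucleotide and indel mutation rates (defaults
#' are mutation-accumulation estimates for a selfing plant:
#' 6.53e-9 substitutions and 0.47e-9 indels per site per generation),
#' generations of seed maintenance before mutagenesis, genome length,
#' and the generation/ploidy weighting used to convert rates into
#' expected counts.
#'
#' @param snp_rate substitutions per site per generation.
#' @param indel_rate indels per site per generation.
#' @param g_pre generations of pre-treatment seed maintenance
#'   (default 10).
#' @param L genome length in bases (default 966e6).
#' @param generation_weighting \code{"haploid"} (factor 1: one genome
#'   copy accumulates mutations per generation) or \code{"diploid"}
#'   (factor 2: both copies mutate and selfing fixes either with equal
#'   probability). The exact accounting is an explicit, documented
#'   parameter: it determines the effective number of site-generations
#'   \code{L * (g_pre + selfing_generations) * factor}.
#' @return a \code{mutation_rate_model} list.
#' @export
mutation_rate_model <- function(snp_rate = 6.53e-9,
                                indel_rate = 0.47e-9,
                                g_pre = 10, L = 966e6,
                                generation_weighting = c("haploid",
                                                         "diploid")) {
  generation_weighting <- match.arg(generation_weighting)
  fail_if(snp_rate < 0 || indel_rate < 0, "rates must be >= 0")
  fail_if(g_pre < 0, "g_pre must be >= 0")
  fail_if(L <= 0, "L must be > 0")
  structure(list(snp_rate = snp_rate, indel_rate = indel_rate,
                 g_pre = g_pre, L = L,
                 generation_weighting = generation_weighting),
            class = "mutation_rate_model")
}

#' Expected spontaneous mutations per line
#'
#' \code{E = rate * site_generations}. By default site-generations are
#' \code{L * (g_pre + selfing_generations) * factor} with the factor
#' set by the model's \code{generation_weighting}; alternatively an
#' explicit \code{site_generations} value overrides the accounting
#' entirely.
#'
#' @param model a \code{\link{mutation_rate_model}}.
#' @param rate_kind \code{"snp"} or \code{"indel"}.
#' @param selfing_generations generations of selfing after treatment
#'   (vectorized; >= 0).
#' @param site_generations optional explicit site-generation total.
#' @return expected mutation count(s) per line.
#' @export
expected_spontaneous_count <- function(model, rate_kind = c("snp",
                                                            "indel"),
                                       selfing_generations,
                                       site_generations = NULL) {
  rate_kind <- match.arg(rate_kind)
  rate <- if (rate_kind == "snp") model$snp_rate else model$indel_rate
  if (is.null(site_generations)) {
    fail_if(any(selfing_generations < 0), "negative generations")
    factor <- if (model$generation_weighting == "diploid") 2 else 1
    site_generations <-
      model$L * (model$g_pre + selfing_generations) * factor
  }
  rate * site_generations
}

#' Pairwise nucleotide diversity (theta pi)
#'
#' Per-site expected heterozygosity with the unbiased small-sample
#' correction, summed over variant sites and averaged over all
#' \code{L} sites:
#' \deqn{\theta_\pi = \frac{1}{L} \sum_s 2 p_s (1 - p_s) \frac{n}{n-1}}
#' with \eqn{p_s} the nonreference allele frequency in a haploid
#' sample of size \eqn{n}.
#'
#' @param variant_allele_counts integer vector of per-site
#'   nonreference allele counts, each in \code{[1, n-1]}.
#' @param n haploid sample size (>= 2).
#' @param L total number of sites (monomorphic + polymorphic).
#' @return a \code{diversity_estimate} list: \code{theta_pi}, \code{n},
#'   \code{S} (variant sites used) and \code{L}.
#' @export
theta_pi <- function(variant_allele_counts, n, L) {
  fail_if(n < 2, "n must be >= 2")
  fail_if(L <= 0, "L must be > 0")
  fail_if(any(variant_allele_counts < 1 | variant_allele_counts > n - 1),
          "allele counts must lie in [1, n-1]")
  p <- variant_allele_counts / n
  tp <- sum(2 * p * (1 - p)) * n / (n - 1) / L
  structure(list(theta_pi = tp, n = n,
                 S = length(variant_allele_counts), L = L),
            class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("theta_pi = %.4g per site (n = %d, S = %d, L = %.3g)\n",
              x$theta_pi, x$n, x$S, x$L))
  invisible(x)
}

#' Windowed theta-pi track
#'
#' Per non-overlapping window of \code{window_bp} bases; the
#' genome-wide estimate equals the length-weighted mean of the
#' windows.
#'
#' @param positions integer vector of variant positions (1-based,
#'   single contig or already offset to a global coordinate).
#' @param allele_counts matching nonreference allele counts.
#' @param n haploid sample size.
#' @param window_bp window size in bases (> 0).
#' @param L contig/genome length.
#' @return data frame \code{(start, end, width, S, theta_pi)}; BED-graph
#'   style, 1-based inclusive.
#' @export
windowed_pi <- function(positions, allele_counts, n, window_bp, L) {
  fail_if(window_bp <= 0, "window_bp must be > 0")
  starts <- seq(1L, L, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, L)
  win <- findInterval(positions, starts)
  df <- data.frame(start = starts, end = ends,
                   width = ends - starts + 1L)
  df$S <- 0L; df$theta_pi <- 0
  for (w in unique(win)) {
    ac <- allele_counts[win == w]
    df$S[w] <- length(ac)
    df$theta_pi[w] <- theta_pi(ac, n, df$width[w])$theta_pi
  }
  df
}

#' Observed heterozygosity per sample
#'
#' Fraction of called genotypes that are heterozygous, per sample.
#'
#' @param x a \code{\link{variant_set}} with genotypes.
#' @return data frame \code{(sample, n_called, n_het, het)}; samples
#'   with no called genotypes get \code{NA} and are flagged in the
#'   \code{missing} column.
#' @export
observed_heterozygosity <- function(x) {
  fail_if(is.null(x$gt), "VariantSet has no genotypes")
  n_called <- colSums(!is.na(x$gt))
  n_het <- colSums(x$gt == 1L, na.rm = TRUE)
  het <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  data.frame(sample = x$samples, n_called = n_called, n_het = n_het,
             het = het, missing = n_called == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
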