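# Small shared helpers: base alphabet, reverse complement on plain
# character vectors (Biostrings handles the sequence-level work; these
# cover per-base bookkeeping where constructing XString objects would
# dominate runtime).

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of short sequences stored as plain strings
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(strsplit(x, "", fixed = TRUE), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

complement_chr <- function(x) {
  unname(COMPLEMENT[x])
}

# stopifnot with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
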