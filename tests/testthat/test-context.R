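test_that("flank extraction returns the literal neighbours for C-reference", {
  #                  12345
  ref <- tiny_ref(chr1 = "AACGT")
  v <- variant_set("chr1", 3, "C", "T")
  w <- extract_flanks(v, ref, context_config(k = 1))
  expect_equal(n_windows(w), 1L)
  expect_equal(unname(w$bases[1, ]), c("A", "G"))
  expect_equal(colnames(w$bases), c("-1", "+1"))
  expect_false(w$flipped[1])
  expect_equal(w$class, "C>T*")
})

test_that("G-reference windows are reverse-complemented", {
  # G at pos 4 of AACGT: plain window "CGT"; after flipping the window
  # is "ACG": upstream neighbour A, downstream neighbour G, and the
  # variant reads as C>T* with alt complemented.
  ref <- tiny_ref(chr1 = "AACGT")
  v <- variant_set("chr1", 4, "G", "A")
  w <- extract_flanks(v, ref, context_config(k = 1))
  expect_true(w$flipped[1])
  expect_equal(w$ref, "C")
  expect_equal(w$alt, "T")
  expect_equal(w$class, "C>T*")
  expect_equal(unname(w$bases[1, ]), c("A", "G"))
})

test_that("edge, overlapping and N-containing windows are excluded", {
  ref <- tiny_ref(chr1 = "CNACGTACGTAC")
  cfg <- context_config(k = 2)
  # pos 1: too close to the contig start
  edge <- variant_set("chr1", 1, "C", "T")
  w1 <- extract_flanks(edge, ref, cfg)
  expect_equal(n_windows(w1), 0L)
  expect_equal(w1$excluded$edge, 1L)
  # pos 4 window covers the N at pos 2
  nn <- variant_set("chr1", 4, "C", "A")
  w2 <- extract_flanks(nn, ref, cfg)
  expect_equal(w2$excluded$n_base, 1L)
  # two SNPs within k of each other exclude each other
  both <- variant_set(c("chr1", "chr1"), c(7, 8), c("A", "C"),
                      c("G", "T"))
  w3 <- extract_flanks(both, ref, cfg)
  expect_equal(n_windows(w3), 0L)
  expect_equal(w3$excluded$overlap, 2L)
})

test_that("indels are rejected from context extraction", {
  ref <- tiny_ref(chr1 = "AACGTACGT")
  ind <- variant_set("chr1", 3, "CG", "C")
  expect_error(extract_flanks(ind, ref), "SNPs only")
  expect_error(sample_null_windows(ind, ref), "SNPs")
})

test_that("null sampling picks only same-base positions within the window", {
  # Cs at positions 3, 6, 9; focal SNP at 6; candidates are 3 and 9
  ref <- tiny_ref(chr1 = "AACAACAACAAA")
  v <- variant_set("chr1", 6, "C", "T")
  cfg <- context_config(k = 1, W = 10, seed = 1,
                        n_null_per_variant = 200)
  nw <- sample_null_windows(v, ref, cfg)
  expect_true(all(nw$pos %in% c(3L, 9L)))
  expect_equal(n_windows(nw), 200L)
  # both candidates appear: uniform draw over two options
  expect_true(all(c(3L, 9L) %in% nw$pos))
  # the draw is not significantly non-uniform
  ct <- table(factor(nw$pos, levels = c(3, 9)))
  expect_gt(chisq.test(ct)$p.value, 1e-4)
  # null windows inherit the focal class
  expect_true(all(nw$class == "C>T*"))
})

test_that("other variant positions are never drawn as null positions", {
  ref <- tiny_ref(chr1 = "AACAACAACAAA")
  v <- variant_set(c("chr1", "chr1"), c(6, 9), c("C", "C"),
                   c("T", "G"))
  cfg <- context_config(k = 1, W = 10, seed = 2,
                        n_null_per_variant = 50)
  nw <- sample_null_windows(v, ref, cfg)
  # only pos 3 remains eligible for both focal SNPs
  expect_true(all(nw$pos == 3L))
  # a focal SNP with zero candidates is skipped and counted
  ref2 <- tiny_ref(chr1 = "AAACAAA")
  v2 <- variant_set("chr1", 4, "C", "T")
  nw2 <- sample_null_windows(v2, ref2, context_config(k = 1, W = 3))
  expect_equal(n_windows(nw2), 0L)
  expect_equal(attr(nw2, "n_skipped"), 1L)
})

test_that("a fixed seed reproduces the null draw exactly", {
  st <- get_small_study()
  snps <- st$fn$variants[classify_variant(st$fn$variants$ref,
                                          st$fn$variants$alt)$label == "SNP"]
  snps <- snps[seq_len(min(200, length(snps)))]
  cfg <- context_config(seed = 99)
  a <- sample_null_windows(snps, st$reference, cfg)
  b <- sample_null_windows(snps, st$reference, cfg)
  expect_identical(a$pos, b$pos)
  expect_identical(a$bases, b$bases)
})

test_that("relative entropy is zero when observed equals null", {
  m <- matrix(c("A", "G",
                "C", "T",
                "G", "A",
                "T", "C"), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("-1", "+1")))
  w <- structure(list(bases = m, ref = rep("C", 4), alt = rep("T", 4),
                      flipped = rep(FALSE, 4), chrom = rep("x", 4),
                      pos = 1:4, class = rep("C>T*", 4), k = 1,
                      excluded = list(edge = 0L, overlap = 0L,
                                      n_base = 0L)),
                 class = "context_windows")
  pr <- relative_entropy_profile(w, w)
  expect_equal(unname(pr$re_bits), c(0, 0))
  expect_equal(pr$p, pr$q)
})

test_that("relative entropy matches the closed form on a point mass", {
  # observed: always G at +1; null: uniform over the four bases.
  # With pseudocount 0, RE = log2(1/0.25) = 2 bits.
  mk <- function(plus1) {
    n <- length(plus1)
    m <- cbind(`-1` = rep("A", n), `+1` = plus1)
    structure(list(bases = m, ref = rep("C", n), alt = rep("T", n),
                   flipped = rep(FALSE, n), chrom = rep("x", n),
                   pos = seq_len(n), class = rep("C>T*", n), k = 1,
                   excluded = list(edge = 0L, overlap = 0L,
                                   n_base = 0L)),
              class = "context_windows")
  }
  obs <- mk(rep("G", 40))
  nul <- mk(rep(c("A", "C", "G", "T"), 10))
  pr <- relative_entropy_profile(obs, nul, pseudocount = 0)
  expect_equal(unname(pr$re_bits["+1"]), 2)
  expect_equal(unname(pr$re_bits["-1"]), 0)
  # the G contribution is the whole signal and positive
  expect_equal(unname(pr$contrib["+1", "G"]), 2)
  # pseudocounts shrink the divergence but keep it positive
  pr2 <- relative_entropy_profile(obs, nul, pseudocount = 0.5)
  expect_lt(unname(pr2$re_bits["+1"]), 2)
  expect_gt(unname(pr2$re_bits["+1"]), 0)
})

test_that("an eight-window hand example reproduces the manual RE", {
  mk <- function(minus1, plus1, cls = "C>T*") {
    n <- length(plus1)
    m <- cbind(`-1` = minus1, `+1` = plus1)
    structure(list(bases = m, ref = rep("C", n), alt = rep("T", n),
                   flipped = rep(FALSE, n), chrom = rep("x", n),
                   pos = seq_len(n), class = rep(cls, n), k = 1,
                   excluded = list(edge = 0L, overlap = 0L,
                                   n_base = 0L)),
              class = "context_windows")
  }
  obs <- mk(c("A", "A", "C", "G"), c("G", "G", "G", "T"))
  nul <- mk(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  pr <- relative_entropy_profile(obs, nul, pseudocount = 0.5)
  p <- (c(A = 2, C = 1, G = 1, T = 0) + 0.5) / 6
  q <- (c(A = 1, C = 1, G = 1, T = 1) + 0.5) / 6
  manual <- sum(p * log2(p / q))
  expect_equal(unname(pr$re_bits["-1"]), manual)
  # class filtering drops windows of other classes
  obs2 <- mk(c("A", "A"), c("G", "G"), cls = "A>G*")
  both <- mk(c(obs$bases[, 1], obs2$bases[, 1]),
             c(obs$bases[, 2], obs2$bases[, 2]))
  both$class <- c(obs$class, obs2$class)
  prf <- relative_entropy_profile(both, nul, class_filter = "C>T*")
  expect_equal(prf$n_obs, 4L)
  expect_error(relative_entropy_profile(both, nul,
                                        class_filter = "C>G*"),
               "no windows")
})

test_that("permutation null has the right shape and behaves under no signal", {
  set.seed(20)
  mk <- function(n) {
    m <- cbind(`-1` = sample(BASES, n, TRUE),
               `+1` = sample(BASES, n, TRUE))
    structure(list(bases = m, ref = rep("C", n), alt = rep("T", n),
                   flipped = rep(FALSE, n), chrom = rep("x", n),
                   pos = seq_len(n), class = rep("C>T*", n), k = 1,
                   excluded = list(edge = 0L, overlap = 0L,
                                   n_base = 0L)),
              class = "context_windows")
  }
  obs <- mk(60); nul <- mk(60)
  perm <- re_permutation_null(obs, nul, n_perm = 50, seed = 4)
  expect_equal(dim(perm), c(50L, 2L))
  expect_true(all(perm >= 0))
  # observed RE under no signal should not exceed the permutation max
  pr <- relative_entropy_profile(obs, nul)
  expect_true(all(pr$re_bits <= apply(perm, 2, max) + 0.2))
  # determinism
  perm2 <- re_permutation_null(obs, nul, n_perm = 50, seed = 4)
  expect_identical(perm, perm2)
})

test_that("k-mer composition matches direct enumeration", {
  ref <- tiny_ref(chr1 = "ACGC")
  km <- kmer_composition(ref, 2)
  got <- setNames(km$count, km$kmer)
  expect_equal(unname(got[c("AC", "CG", "GC")]), c(1, 1, 1))
  expect_equal(sum(km$count), 3)
  expect_equal(sum(km$frequency), 1)
  # homopolymer: one k-mer only
  km2 <- kmer_composition(tiny_ref(chr1 = "AAAA"), 1)
  expect_equal(km2$count[km2$kmer == "A"], 4)
  expect_equal(sum(km2$count), 4)
  # k = 1 equals alphabetFrequency on a bigger sequence
  st_ref <- tiny_ref(chr1 = paste(sample(BASES, 500, TRUE),
                                  collapse = ""))
  km3 <- kmer_composition(st_ref, 1)
  af <- Biostrings::alphabetFrequency(st_ref)[1, c("A", "C", "G", "T")]
  expect_equal(setNames(km3$count, km3$kmer)[names(af)],
               setNames(as.numeric(af), names(af)))
  # both_strands doubles the total and symmetrizes
  km4 <- kmer_composition(ref, 2, both_strands = TRUE)
  g4 <- setNames(km4$count, km4$kmer)
  expect_equal(unname(g4["AC"]), unname(g4["GT"]))
  expect_equal(sum(km4$count), 6)
})

test_that("context FASTA round-trips through Biostrings", {
  ref <- tiny_ref(chr1 = "AACGTAC")
  v <- variant_set("chr1", 3, "C", "T")
  w <- extract_flanks(v, ref, context_config(k = 2))
  path <- tempfile(fileext = ".fa")
  write_context_fasta(w, path)
  back <- Biostrings::readDNAStringSet(path)
  expect_equal(as.character(back[[1]]), "AACGT")
  expect_equal(names(back), "chr1:3:C>T*")
})
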