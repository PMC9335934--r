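# ---- helpers -------------------------------------------------------

patch_seq <- function(s, pos, repl) {
  paste0(substr(s, 1, pos - 1), repl,
         substr(s, pos + nchar(repl), nchar(s)))
}

# A 12 kb contig carrying three hand-built genes:
#  tx1 (+): exon 91-130, CDS 101-118 = ATG GCT TGG TAT CAA TAA
#  tx2 (+): exons 201-260 and 341-400 (intron 261-340), CDS 211-240
#  tx3 (-): exon/CDS 1001-1009 = revcomp(ATG GCT TAA) = TTAAGCCAT
hand_gene_fixture <- function() {
  s <- strrep("ACGT", 3000)
  s <- patch_seq(s, 101, "ATGGCTTGGTATCAATAA")
  s <- patch_seq(s, 211, "ATG")
  s <- patch_seq(s, 238, "TAA")
  s <- patch_seq(s, 1001, "TTAAGCCAT")
  gm <- gene_models(
    transcripts = data.frame(
      tx_id = c("tx1", "tx2", "tx3"),
      gene_id = c("g1", "g2", "g3"),
      chrom = "chr1", strand = c("+", "+", "-"),
      start = c(91L, 201L, 1001L), end = c(130L, 400L, 1009L),
      stringsAsFactors = FALSE),
    exons = data.frame(
      tx_id = c("tx1", "tx2", "tx2", "tx3"),
      start = c(91L, 201L, 341L, 1001L),
      end = c(130L, 260L, 400L, 1009L)),
    cds = data.frame(
      tx_id = c("tx1", "tx2", "tx3"),
      start = c(101L, 211L, 1001L), end = c(118L, 240L, 1009L),
      phase = 0L))
  list(ref = tiny_ref(chr1 = s), gm = gm, seq = s)
}

label_for <- function(fx, pos, ref, alt, tx) {
  v <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                  stringsAsFactors = FALSE)
  out <- classify_consequence(v, fx$gm, fx$ref)
  out$consequence[out$transcript == tx & !is.na(out$transcript)]
}

# ---- indel spectra -------------------------------------------------

test_that("indel length spectrum counts signed lengths and insertions", {
  v <- data.frame(ref = c("A", "AT", "ATT", "ATTTT", "G"),
                  alt = c("AG", "A", "A", "A", "GAAA"),
                  stringsAsFactors = FALSE)
  sp <- indel_length_spectrum(v, "toy")
  expect_equal(sp$signed_length, c(-4L, -2L, -1L, 1L, 3L))
  expect_equal(sp$count, rep(1L, 5))
  expect_equal(attr(sp, "insertion_fraction"), 2 / 5)
  expect_error(indel_length_spectrum(
    data.frame(ref = "A", alt = "G")), "indel-class")
})

test_that("indel histogram matches a brute-force recount", {
  set.seed(8)
  n <- 300
  len <- sample(c(-10:-1, 1:10), n, replace = TRUE,
                prob = c(rep(2, 10), rep(1, 10)))
  mk <- function(l) {
    if (l < 0) list(ref = paste0("A", strrep("T", -l)), alt = "A")
    else list(ref = "A", alt = paste0("A", strrep("C", l)))
  }
  alle <- lapply(len, mk)
  v <- data.frame(ref = vapply(alle, `[[`, "", "ref"),
                  alt = vapply(alle, `[[`, "", "alt"),
                  stringsAsFactors = FALSE)
  sp <- indel_length_spectrum(v)
  manual <- table(len)
  expect_equal(setNames(sp$count, sp$signed_length),
               setNames(as.integer(manual), names(manual)))
  expect_equal(attr(sp, "insertion_fraction"), mean(len > 0))
})

test_that("single-bp indel base identity is tallied per direction", {
  v <- data.frame(ref = c("CA", "TG", "C", "G", "AA"),
                  alt = c("C", "T", "CG", "GT", "A"),
                  stringsAsFactors = FALSE)
  id <- single_bp_identity(v)
  expect_equal(unname(id$deleted[c("A", "G")]), c(2L, 1L))
  expect_equal(sum(id$deleted), 3L)
  expect_equal(unname(id$inserted[c("G", "T")]), c(1L, 1L))
  expect_error(single_bp_identity(
    data.frame(ref = "CAA", alt = "C")), "1-bp")
})

# ---- SNP consequences against hand-built genes ---------------------

test_that("SNP consequences match hand-computed labels on a plus gene", {
  fx <- hand_gene_fixture()
  # codon2 GCT(Ala): C>G gives GGT(Gly)
  expect_equal(label_for(fx, 105, "C", "G", "tx1"), "missense")
  # GCT -> GCC is still Ala
  expect_equal(label_for(fx, 106, "T", "C", "tx1"), "synonymous")
  # codon3 TGG -> TGA
  expect_equal(label_for(fx, 109, "G", "A", "tx1"), "stop_gained")
  # stop codon TAA -> TCA (Ser)
  expect_equal(label_for(fx, 117, "A", "C", "tx1"), "stop_lost")
  # start codon ATG -> GTG
  expect_equal(label_for(fx, 101, "A", "G", "tx1"), "start_lost")
  # untranslated exon bases
  expect_equal(label_for(fx, 95, substr(fx$seq, 95, 95), "A", "tx1"),
               "5' UTR")
  expect_equal(label_for(fx, 125, substr(fx$seq, 125, 125), "C",
                         "tx1"), "3' UTR")
})

test_that("intron, splice-region and flank labels follow the geometry", {
  fx <- hand_gene_fixture()
  b <- function(p) substr(fx$seq, p, p)
  alt_of <- function(p) setdiff(c("A", "C"), b(p))[1]
  # deep intron of tx2 (intron 261-340)
  expect_equal(label_for(fx, 300, b(300), alt_of(300), "tx2"),
               "intron")
  # 4 bases into the intron: within the 8-base intronic splice region
  expect_equal(label_for(fx, 265, b(265), alt_of(265), "tx2"),
               "splice_region")
  expect_equal(label_for(fx, 336, b(336), alt_of(336), "tx2"),
               "splice_region")
  # first exonic base of exon 2 (non-coding, within 3 of the junction)
  expect_equal(label_for(fx, 341, b(341), alt_of(341), "tx2"),
               "splice_region")
  # non-coding exon-2 base away from the junction, after the CDS: 3' UTR
  expect_equal(label_for(fx, 370, b(370), alt_of(370), "tx2"),
               "3' UTR")
  # flanks are strand-aware
  expect_equal(label_for(fx, 50, b(50), alt_of(50), "tx1"), "upstream")
  expect_equal(label_for(fx, 900, b(900), alt_of(900), "tx3"),
               "downstream")
  expect_equal(label_for(fx, 1100, b(1100), alt_of(1100), "tx3"),
               "upstream")
  # beyond flank_bp of everything: a single intergenic row
  v <- data.frame(chrom = "chr1", pos = 11000, ref = b(11000),
                  alt = alt_of(11000), stringsAsFactors = FALSE)
  out <- classify_consequence(v, fx$gm, fx$ref)
  expect_equal(nrow(out), 1L)
  expect_true(is.na(out$transcript))
  expect_equal(out$consequence, "intergenic")
})

test_that("minus-strand codons are read on the coding strand", {
  fx <- hand_gene_fixture()
  # tx3 codon2 is GCT (Ala), read from genomic 1006-1004; genomic
  # G1005>C makes it GGT (Gly)
  expect_equal(label_for(fx, 1005, "G", "C", "tx3"), "missense")
  # genomic C1006>T reads as G>A on the coding strand: GCT -> ACT (Thr)
  expect_equal(label_for(fx, 1006, "C", "T", "tx3"), "missense")
  # third codon position of codon2 is genomic 1004 (A, pairs with T);
  # A>G reads T>C: GCT -> GCC, still Ala
  expect_equal(label_for(fx, 1004, "A", "G", "tx3"), "synonymous")
  # destroying the start codon: genomic T1009>G reads A>C
  expect_equal(label_for(fx, 1009, "T", "G", "tx3"), "start_lost")
})

# ---- indel consequences --------------------------------------------

test_that("CDS indels are frameshift unless the net change is a multiple of 3", {
  fx <- hand_gene_fixture()
  s <- fx$seq
  # delete one CDS base (105)
  expect_equal(label_for(fx, 104, substr(s, 104, 105),
                         substr(s, 104, 104), "tx1"), "frameshift")
  # delete three CDS bases (105-107)
  expect_equal(label_for(fx, 104, substr(s, 104, 107),
                         substr(s, 104, 104), "tx1"),
               "inframe_deletion")
  # insert one base between two CDS positions
  expect_equal(label_for(fx, 104, substr(s, 104, 104),
                         paste0(substr(s, 104, 104), "A"), "tx1"),
               "frameshift")
  # insert three bases
  expect_equal(label_for(fx, 104, substr(s, 104, 104),
                         paste0(substr(s, 104, 104), "AAA"), "tx1"),
               "inframe_insertion")
  # a 3-bp deletion straddling the CDS boundary removes a non-multiple
  # of 3 of coding bases (99-101: one CDS base) -> frameshift
  expect_equal(label_for(fx, 98, substr(s, 98, 101),
                         substr(s, 98, 98), "tx1"), "frameshift")
  # deep-intron deletion with no CDS change
  expect_equal(label_for(fx, 299, substr(s, 299, 301),
                         substr(s, 299, 299), "tx2"), "intron")
})

# ---- translation oracle over random fixtures -----------------------

test_that("internal-CDS SNP labels agree with a translate-and-compare oracle", {
  set.seed(101)
  sense <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  internal <- setdiff(sense, "ATG")
  n_genes <- 25
  per_gene <- 20
  checked <- 0L
  for (g in seq_len(n_genes)) {
    strand <- if (g %% 2 == 0) "-" else "+"
    n_codons <- 20L
    cds <- paste0("ATG",
                  paste(sample(internal, n_codons - 2, TRUE),
                        collapse = ""),
                  "TAA")
    genomic <- if (strand == "+") cds else revcomp_chr(cds)
    pad <- strrep("ACGT", 100)
    s <- paste0(pad, genomic, pad)
    start <- nchar(pad) + 1L
    end <- start + nchar(genomic) - 1L
    ref <- tiny_ref(chr1 = s)
    gm <- gene_models(
      transcripts = data.frame(tx_id = "t", gene_id = "g",
                               chrom = "chr1", strand = strand,
                               start = start, end = end,
                               stringsAsFactors = FALSE),
      exons = data.frame(tx_id = "t", start = start, end = end),
      cds = data.frame(tx_id = "t", start = start, end = end,
                       phase = 0L))
    # SNPs restricted to internal codons (2 .. n-1)
    offs <- sample(4:(3 * (n_codons - 1)), per_gene, replace = FALSE)
    for (o in offs) {
      gpos <- if (strand == "+") start + o - 1L
              else end - o + 1L
      rb <- substr(s, gpos, gpos)
      ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
      got <- label_for(list(ref = ref, gm = gm), gpos, rb, ab, "t")
      # oracle: mutate the coding sequence directly and translate
      cds_alt <- cds
      substr(cds_alt, o, o) <- if (strand == "+") ab
                               else unname(c(A = "T", C = "G",
                                             G = "C", T = "A")[ab])
      prot_ref <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds)))
      prot_alt <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds_alt)))
      body_alt <- substr(prot_alt, 1, nchar(prot_alt) - 1)
      want <- if (grepl("\\*", body_alt)) "stop_gained"
              else if (identical(prot_ref, prot_alt)) "synonymous"
              else "missense"
      expect_equal(got, want,
                   info = sprintf("gene %d strand %s offset %d %s>%s",
                                  g, strand, o, rb, ab))
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 500L)
})

# ---- summaries -----------------------------------------------------

test_that("consequence summary proportions sum to 100 percent", {
  rec <- data.frame(consequence = c("missense", "missense",
                                    "synonymous", "intron"))
  sm <- consequence_summary(rec, "toy")
  expect_equal(sum(sm$proportion), 100)
  expect_equal(sm$count[sm$consequence == "missense"], 2L)
})

test_that("frameshift share of coding follows its definition", {
  # all coding consequences are frameshifts
  expect_equal(frameshift_fraction_of_coding(c(frameshift = 7)), 100)
  # non-coding classes are excluded from the denominator
  cnt <- c(frameshift = 2, missense = 3, synonymous = 5, intron = 100,
           intergenic = 50)
  expect_equal(frameshift_fraction_of_coding(cnt), 100 * 2 / 10)
  # case-insensitive label matching
  cnt2 <- c(Frameshift = 1, Missense = 3)
  expect_equal(frameshift_fraction_of_coding(cnt2), 25)
  # data frame input
  df <- data.frame(consequence = c("frameshift", "missense"),
                   count = c(1L, 1L))
  expect_equal(frameshift_fraction_of_coding(df), 50)
  expect_error(frameshift_fraction_of_coding(c(intron = 5)),
               "no coding")
})
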