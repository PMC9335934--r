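---
title: "Methods: isolating and characterising induced mutations with fnmut"
author: "fnmut authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isolating and characterising induced mutations with fnmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnmut)
```

# The scientific problem

Fast-neutron (FN) irradiation of seed induces DNA damage that, after
several generations of self-fertilisation, fixes as homozygous
mutations in derived lines. Whole-genome sequencing of a mutagenized
cohort observes three superimposed layers of variation:

1. **Standing variation** — differences between the parental line and
   the reference genome, and variants segregating in the species
   (observable in a diversity panel).
2. **De novo induced variation** — the mutations the experiment is
   about.
3. **Technical artifacts** — miscalled heterozygotes, low-coverage
   calls, and residual heterogeneity shared across lines that trace to
   incomplete inbreeding of the source seed rather than to mutagenesis.

`fnmut` implements the full procedure for separating these layers and
characterising the induced mutations: the de novo filter chain, the
strand-collapsed mutational spectrum, relative-entropy context
profiles, indel and coding-consequence analysis, diversity statistics,
and a synthetic-data generator with a planted truth table for
validating all of the above.

# The de novo filter chain

`isolate_de_novo()` applies, in order:

1. **Known-variant subtraction** (`subtract_known`): treatment
   variants identical in (chromosome, position, ref, alt) to any
   parental or panel variant are removed. Variants sharing only a
   position are retained but flagged
   (`position_collision`), because a different allele at a known site
   is still a candidate mutation; set
   `filter_config(drop_position_collisions = TRUE)` for the stricter
   behaviour. All comparisons happen after left-alignment
   normalisation (`normalize_variants`), so equivalent indel encodings
   subtract correctly.
2. **Deletion masks** (`apply_masks`): regions deleted in the parental
   line relative to the reference cannot be ascertained; any variant
   whose reference span intersects a mask interval is removed.
3. **Quality control**: variant quality at least `min_qual` (default
   30) and carrier read depth at least `min_depth` (default 5).
4. **The carrier rule**: a true induced mutation, fixed by selfing,
   should be *homozygous* in *exactly one* line. Heterozygous
   candidates and candidates carried by several lines are removed —
   unless the carriers form one sibling family and
   `allow_family_sharing = TRUE`, since siblings derive from a single
   mutagenized plant and legitimately share mutations.

Every input variant receives a provenance label (`known`, `masked`,
`low_qual`, `heterozygous`, `multi_carrier`, `low_depth`,
`not_called`, `retained`, ...), so each removal is attributable to one
filter and filter tallies are auditable. Per-line totals more than
three times the cohort median are flagged as outliers in the per-line
table — a line accumulating far more candidates than its cohort is
usually contaminated or mislabelled rather than hypermutated.

Standing variation is partitioned by `partition_by_frequency()` into
**rare** (nonreference allele count 1–2) and **common** (3 or more)
strata. Rare standing variants are the youngest and least exposed to
purifying selection, making them the natural comparison set for new
mutations.

# The strand-collapsed spectrum

Sequencing cannot identify the strand of origin of a substitution, so
the 12 ordered base changes collapse into 6 classes, each pooling a
change with its reverse complement; the canonical representative has
reference base A or C (`C>T*` = C→T plus G→A). `spectrum_table()`
computes class counts and fractions and the transition/transversion
ratio Ts/Tv = (C>T* + A>G*) / (other four classes); a set with no
transversions yields `Inf` with an explicit degenerate flag.

Per-line summaries (`per_line_summary`) report the cohort mean and the
**sample** standard deviation (n − 1 denominator); with a single line
the SD is `NA` and flagged rather than silently zero.
`snp_indel_association()` computes the squared Pearson correlation of
per-line SNP and indel counts, a paired t-test on the same pairs, and
a type-II two-way ANOVA (via `car::Anova`) of total counts on
radiation dosage and selfing generations, both treated as categorical.

# Flanking-context relative-entropy profiles

For each SNP, `extract_flanks()` takes a window of `2k + 1` reference
bases centred on the variant (`k = 2` by default — the motif signal of
interest lives within two bases, and wider windows dilute counts).
Windows whose central base is G or T are reverse-complemented so the
central base is always A or C; upstream/downstream exchange
accordingly. Windows truncated by contig edges, containing another
variant position, or containing a non-ACGT base are excluded and
counted. Indels are rejected outright: an indel has multiple
equiprobable alignments, so "its" flanking context is not observable.

The null model (`sample_null_windows()`) draws, per focal SNP,
positions within ±`W` bases (default `W = 50`) that carry the *same
reference base*, excluding all variant positions. The ±50 window is
wide enough to contain many same-base positions (a ~25% per-base
frequency gives ~25 candidates per side) yet narrow enough that the
null inherits local composition — GC content varies along a genome,
and a genome-wide null would confound local composition with
mutational preference. Null windows inherit the focal variant's
mutation class so class-filtered profiles compare like with like.

`relative_entropy_profile()` scores each offset by the
Kullback–Leibler divergence (bits) between observed and null base
frequencies, with an additive pseudocount of 0.5 per base (Jeffreys
prior) so that a base absent from a small observed set does not
produce infinite divergence. Signed per-base contributions
`p log2(p/q)` make the direction of enrichment readable (positive =
overrepresented). `re_permutation_null()` shuffles window labels
between the observed and null sets to give the distribution of RE
magnitudes expected when context carries no signal; an offset is only
interpreted when it exceeds, say, the permutation 99th percentile.

# Indels and coding consequences

`indel_length_spectrum()` tabulates signed lengths (negative =
deletion) and the insertion fraction; plots cap the display at ±20 bp
but the histogram retains all lengths. `single_bp_identity()` tallies
the inserted/deleted base of 1-bp events — FN data show a strong A/T
excess there.

`classify_consequence()` is a minimal, deterministic consequence
classifier over GFF3-derived gene models: one label per
(variant, transcript) pair with precedence
frameshift/stop_gained/stop_lost/start_lost > inframe > missense >
splice_region > synonymous > UTR > intron. A coding indel is a
frameshift exactly when its net CDS-overlap length is not a multiple
of three. The splice region spans 3 exonic and 8 intronic bases from
each junction (donor/acceptor sites are folded into
`splice_region`). Variants outside a transcript but within `flank_bp`
(default 5000) are upstream/downstream by strand; everything else is
intergenic. `frameshift_fraction_of_coding()` reports frameshifts as
a percentage of all coding-class consequences.
It is deliberately not a full effect predictor: no regulatory
features, no existing-variation lookup, no paralog annotation.

# Diversity and spontaneous expectations

`theta_pi()` computes pairwise nucleotide diversity with the unbiased
per-site estimator `2 p (1 − p) · n/(n − 1)` summed over variant sites
and averaged over all `L` sites, for a haploid sample of inbred
lines. For 1430 homozygous singletons in n = 27 lines over a 966 Mb
genome this gives 1.1 × 10⁻⁷ — orders of magnitude below the standing
diversity of the species, confirming the de novo set is not residual
standing variation.

`mutation_rate_model()` holds spontaneous per-generation rates
(defaults 6.53 × 10⁻⁹ substitutions and 0.47 × 10⁻⁹ indels per site)
and `expected_spontaneous_count()` converts them to expected counts
per line via `E = rate × site_generations`. Two accountings are
exposed on purpose: the default derives site-generations as
`L × (g_pre + selfing_generations) × factor` (haploid factor 1 or
diploid factor 2), while `site_generations` can be passed explicitly
— published expectations are sometimes stated without their exact
generation/ploidy accounting, and an explicit override makes any
target reproducible without guessing.

# The synthetic-data generator

`simulate_study()` generates a complete study with known truth:

- **Reference**: i.i.d. bases at 34% GC (typical for a plant genome)
  across `contigs` (default 2 × 2 Mb — large enough for ~10⁴ planted
  events with realistic spacing, small enough for desk-scale runtime).
- **Gene models**: non-overlapping multi-exon genes on both strands
  with valid ATG...stop CDS (no internal stop); the coding sequence is
  patched into the reference so models and sequence agree.
- **Parental variants**: 1.5 SNPs and 0.25 indels per kb versus the
  reference, and deletion masks covering 3.8% of the genome in
  intervals of mean length 5 kb — mirroring the observed density of
  parent-vs-reference differences and masked fraction in real
  cohorts.
- **Diversity panel**: 30 lines at 2 SNPs and 0.35 indels per kb with
  allele counts following a 1/i law (the neutral frequency-spectrum
  shape), realised *exactly* in the genotypes so frequency
  partitioning is deterministic.
- **Treatment cohort**: 27 lines; per-line Poisson(53) SNPs and
  Poisson(32) indels (matching observed cohort means), homozygous,
  planted at unmasked, non-parental, non-panel, mutually
  non-overlapping sites (minimum spacing 60 bp so flank windows never
  collide). SNP classes follow the six-class law
  (C>T* 0.458, A>G* 0.220, C>A* 0.100, C>G* 0.055, A>T* 0.090,
  A>C* 0.077) with a CpG-conditional boost (default 3×) for C>T*;
  indels are 71.5% deletions with geometric lengths (p = 0.6, cap 50)
  and an 80% A/T bias among 1-bp events.
- **Noise layers**, each off by default and each tagged in the truth
  table: spurious heterozygous calls (`het_rate`), low-coverage calls
  (`low_depth_rate`), and heterogeneity variants shared by 2–4
  non-sibling lines (`n_heterogeneity`) — exactly the signatures the
  filter chain must remove, enabling per-filter validation.

Everything derives deterministically from one master seed (stage
offsets keep streams independent), so two runs with the same
configuration are byte-identical on disk.

```{r, eval = FALSE}
st <- simulate_study(sim_config(seed = 1), out_dir = "simdir")
report <- run_pipeline(st, out_dir = "report")
```

# Parameter conventions and defaults at a glance

| Parameter | Default | Rationale |
|---|---|---|
| `min_qual`, `min_depth` | 30, 5 | conventional confident-call floor |
| per-line outlier rule | > 3 × median | flags contaminated lines |
| context `k` | 2 | motif signal is local; counts stay dense |
| null window `W` | ±50 | local composition, ample candidates |
| pseudocount | 0.5 | Jeffreys prior; finite RE at small n |
| SD convention | sample (n − 1) | inference about the cohort, not a census |
| splice region | 3 exonic / 8 intronic | standard splice-region extent |
| `flank_bp` | 5000 | conventional upstream/downstream window |
| rare/common split | allele count ≤ 2 / ≥ 3 | singletons+doubletons are youngest |
| `site_generations` | derived or explicit | published accountings differ |

# Limitations

- The consequence classifier ignores regulatory annotation, splice
  isoform creation, and compound events; MNPs are not classified.
- Indel context profiles are intentionally unsupported (alignment
  ambiguity).
- The simulator plants variants at the genotype level; it does not
  simulate reads, mapping error, or structural variants beyond small
  indels, and planted events never overlap (real tandem events are
  rarer than the spacing margin makes them here, but they do exist).
- `theta_pi` assumes a haploid sample of fully inbred lines; residual
  heterozygosity biases it upward (check `observed_heterozygosity`).
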