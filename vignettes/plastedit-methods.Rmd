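---
title: "Methods: PPR-code target prediction and C-to-U editing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPR-code target prediction and C-to-U editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastedit)
```

# The problem

Plastid transcripts in flowering plants undergo C-to-U RNA editing.
Site recognition is provided by pentatricopeptide-repeat (PPR) proteins:
tandem arrays of 35-amino-acid helix-loop-helix motifs that bind the RNA
immediately 5' of the edited cytidine, one motif per base. The amino acids
at positions 5 and last ("35") of each motif largely determine which base
that motif prefers — the PPR-RNA recognition code. `plastedit` implements
the computational chain by which an orphan editing factor is matched to an
orphan editing site: code-based alignment scoring with genome-wide z-score
normalization, editing quantification from RNA-seq pileups across an
expression series of genotypes, expression quantification (RPKM, qPCR),
and cis-element co-evolution profiling across species that have retained
or lost the editing event.

# Alignment scoring and the code table

A factor is a `ppr_array`: an ordered list of motifs, each with its class
(P1/P2/L1/L2/S1/S2/E1/E2/DYW) and its (aa5, aa_last) combination. The
`code_table` maps each (aa5, aa_last) combination to four log-likelihood
ratios, one per RNA base, derived from observed motif/base association
frequencies. The alignment score of a factor against a site is the sum of
the per-position log-likelihood ratios, motifs N-to-C against the window
5'-to-3':

$$S(\text{factor}, \text{site}) = \sum_{i \in \text{scored motifs}}
  \mathrm{LLR}\big(aa5_i, aaL_i, b_i\big)$$

Numerical choices:

* **Unknown combinations score 0.** Non-canonical (aa5, aa_last)
  combinations have poorly characterized selectivity; 0 is the neutral
  log-likelihood. This is the table's `default_score` and is configurable.
* **Which motifs are scored** is caller-controlled via the array's
  `scored` mask; by default every motif whose combination has a table
  entry contributes. The class composition of real editing factors varies
  and no fixed rule (e.g. "P and S only") is imposed.
* **T and U are interchangeable** on input; U is canonical internally
  (genome files use T; the code is defined on RNA).
* **No published code-table values ship with the package.** The table is a
  required input; `inst/extdata/example_code_table.tsv` is a synthetic
  example for documentation only, and every test builds its own table.

# Candidate sites and z-scores

Essentially all plastid editing sites sit in a YC context: the edited C is
preceded by a pyrimidine. `enumerate_candidate_sites()` therefore scans
both strands of every record for C preceded 5' by C or T, and attaches the
upstream window. The alignment register places the C-terminal-most scored
motif at position −4 relative to the edited C (the canonical PPR-code
convention); the `offset` parameter exposes the register because it is a
modelling choice, not a law.

* Windows that run off a sequence end are left-padded with `N` (scoring
  `default_score`) so the candidate census does not depend on the factor's
  length; `pad_edges = FALSE` drops them instead. Plastid genomes are
  circular; `circular = TRUE` wraps windows, but the default is linear,
  matching coordinate systems that append constructs to the record end.
* Coordinates are 1-based inclusive, forward-strand, with an explicit
  strand column — the convention of GFF and of editing-site names such as
  *rps14-2* (37092).

Raw scores are not comparable between factors (arrays differ in length and
composition), so each factor's scores are normalized against its own
genome-wide population of candidate alignments:
$z = (s - \mu)/\sigma$ with the **population** (divide-by-n) standard
deviation — the candidate set is the complete population of alignments,
not a sample. A factor whose alignments all score identically has no
usable spread; `scan_factor()` raises an error for it, and
`rank_factors_for_site()` reports such factors with `NA` z and a warning
rather than dropping them silently. Ties in ranking are broken
deterministically by (seq_id, position, strand).

# Editing detection

Editing extent at a site is
$100 \cdot n_T / (n_T + n_C)$ percent, from strand-aware base counts.
`detect_candidate_events()` applies two strict filters: the position must
be genomically encoded C on the examined strand, the edited-read count
must be **strictly greater than 10**, and the edited fraction **strictly
greater than 1%** (both configurable via `filter_config()`). Strictness
matters at the boundary: 10 edited reads of 10 is rejected, 11 of 1,000
(1.1%) is accepted, 50 of 10,000 (0.5%) is rejected.

`call_induced_events()` implements the three-rule caller for an
over-expression series (genotypes `low_expr` / `control` / `over_expr`,
three replicates each by default):

1. detected (as above) in **every** over-expressor replicate;
2. not in a mis-alignment-prone homopolymer context — `(T)nC(T)n` on the
   forward strand, `(A)nG(A)n` for a reverse-strand site read on the
   forward strand. The run length *n* is not fixed by any first
   principle; the default is 2 per flank, configurable, and flagged sites
   are *reported* in a side table for review, never silently discarded;
3. replicate-mean fractions follow low ≤ control < over-expressor. The
   comparison uses an additive `pattern_tolerance` (default 0 percentage
   points); the low-vs-control comparison is non-strict and
   control-vs-over is strict, the only internally consistent reading of
   an "equal or lower … lower" pattern.

`quantify_known_sites()` reports per-replicate fractions with mean and
standard error (sample SD / √n; `NA` for a single replicate; uncovered
sites are missing, not zero).

# Expression

RPKM is computed as $10^9 \cdot R_i / (T_i \cdot L)$ with $T_i$ the total
reads over the *counted gene set*, built by `select_gene_set()`: rRNA and
tRNA genes, the original trans-spliced rps12 features, and genes wholly
inside one designated inverted-repeat copy are excluded (designating both
IR copies is a configuration error; designating none only warns, since
annotations often lack IR spans). Gene length defaults to the exon union
where exon features exist, with a locus-span alternative.
`build_modified_annotation()` appends a concatenated rps12 construct
(2,519 nt, introns at relative positions 175–1664 and 1897–2433) to the
plastid record and shifts the first ycf3 intron one nucleotide downstream,
so junction-spanning reads can be counted; with a 154,478 bp plastid
record these land at 154479–156997, 154653–156142, 156375–156911 and
43753–44466.

qPCR expression is normalized with the efficiency-corrected ratio
$(1+E_t)^{C_{max}-Cq_t} / (1+E_r)^{C_{max}-Cq_r}$ with `max_cycles`
defaulting to 35. `pair_editing_expression()` joins per-line replicate
editing and expression into the mean ± SE table used for
editing-vs-expression plots; no correlation statistic is computed, since
the relationship is assessed graphically and a parametric statistic would
suggest more than the design supports.

# Cis-element co-evolution

Orthologous windows (default span −20…+4 around the edited position,
covering the PPR footprint and the edited codon) are partitioned by the
genomic state at position 0: C (editing still required) versus T (editing
lost). `position_profile()` flags a position as *highlighted* when the two
groups' observed symbol sets differ — either group contains a nucleotide
absent from the other — and *faded* otherwise. This across-group
symbol-set reading is the minimal formalization of "no new nucleotides
introduced in either group"; a within-group consensus variant is available
via `within_group = TRUE` without any claim as to which is canonical.
`translate_window()` trims to codon phase, drops partial codons and uses
the standard genetic code (so the edited codon pair CCA→proline versus
CUA→leucine is reproduced exactly).

# The synthetic-data generator

Every stage is testable without external data. The generator emulates the
study design the analyses assume — it does not emulate real organellar
data in full:

* `sim_genome()`: i.i.d. bases at a set GC fraction (default 0.36, typical
  of plastid genomes). Real plastid genomes have strong local composition
  structure, repeats and an inverted repeat; none of that is modelled, so
  passing tests demonstrate correctness of the computation, not
  performance on real genomes.
* `plant_target()` writes a factor's `preferred_window()` upstream of a
  chosen position, makes the site YC, and returns a collision-checked
  manifest. By construction the planted site attains the factor's maximal
  achievable raw score, which is what makes rank-1 recovery a theorem
  rather than a hope. `simulate_study()` additionally constructs the
  genuine site outside homopolymer decoy contexts, so that only its
  deliberately planted decoys carry the `(T)nC(T)n` signature.
* `simulate_pileups()`: fixed per-site depth (default 1,000); edited reads
  are Binomial(depth, f(1−e) + (1−f)e/3) with uniform miscall rate
  e = 0.001 spread equally over the three alternative bases. Sequencing
  error in real data is neither uniform nor position-independent; the
  detection filters are designed to absorb error, so a simple model
  suffices to exercise them. A fixed depth isolates binomial sampling
  noise; coverage variation would only widen the recovery bands.
* Default genotype fractions for induced-site simulations are
  0.02 / 0.50 / 0.95 (low / control / over), a strong induction pattern
  mirroring a factor whose editing is unsaturated in the wild type and
  near-complete on over-expression.
* `simulate_counts()` allocates reads multinomially with probability
  proportional to RPKM × length; `simulate_qpcr()` inverts the
  normalization formula exactly before adding Gaussian Cq noise;
  `simulate_seed_segregation()` draws each seed white with probability
  1/4 — the Mendelian expectation for a selfed heterozygote carrying a
  recessive embryo-lethal allele (3:1 green:white).
* All generators are reproducible under an integer seed.

Problem sizes used in the test suite and acceptance script — genomes of
0.3–5 kb for scans, one plastid-sized (154,478 bp) genome for the
candidate census, 20 seeds for recovery runs, 1,000 sites at depth 1,000
for fraction recovery — were chosen so that each property is measured with
comfortable statistical margin while the whole suite runs in well under a
minute per module.

# A worked example

```{r example}
tab <- read_code_table(system.file("extdata", "example_code_table.tsv",
                                   package = "plastedit"))
arr <- ppr_array("factorA", data.frame(
  motif_class = rep(c("P1", "L1", "S1"), length.out = 10),
  aa5     = c("T", "S", "N", "T", "S", "N", "P", "G", "N", "T"),
  aa_last = c("D", "N", "D", "N", "N", "S", "D", "D", "N", "D")))
preferred_window(arr, tab)

g <- sim_genome(3000, seed = 42)
pt <- plant_target(g, arr, tab, position = 1500, strand = "+")
sc <- scan_factor(arr, pt$genome, tab)
sc$top_hits[1, c("position", "strand", "window", "raw_score", "z_score")]
```

# Known limitations

* The recognition code is treated as position-independent: every scored
  motif contributes with equal weight. Real factors likely weight motifs
  unequally, which is one reason code-score rank alone over-predicts
  targets; the editing-detection stage exists precisely to separate
  predicted from realized sites.
* Pileups are consumed from TSV; producing them from alignments (BAM) is
  an upstream step outside the package.
* The co-evolution module consumes pre-aligned, pre-extracted windows;
  alignment and tree inference are upstream.
* The inverted-repeat exclusion relies on a user-supplied IR span; the
  package does not detect IRs.
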