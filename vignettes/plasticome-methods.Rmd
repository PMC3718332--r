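---
title: "Methods: detecting the plastic fraction of an archaeal chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting the plastic fraction of an archaeal chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plasticome dissects small circular prokaryotic chromosomes — the motivating
system is a *Sulfolobus islandicus*-like crenarchaeal genome of ~2.5 Mb at
35% GC — into their conserved backbone and their plastic fraction: CRISPR
arrays, integrated viral and plasmid elements, clusters of atypical genes,
IS elements and MITEs, plus the replication-origin landscape and a
molecular-clock view of strain divergence. This vignette records the models
behind each detector, the defaults and why they were chosen, and what the
bundled simulator does and does not emulate.

## Genome model and coordinates

A genome is a single replicon: one DNA string over `{A,C,G,T,N}` with a
circular/linear flag and an ordered feature table (CDS, tRNA, rRNA,
repeat_region, misc). All coordinates, in memory and on disk, are 1-based
inclusive — the GenBank/GFF3 convention; features crossing the circular
junction are stored as two spans sharing one id. `N` never matches any base
in any scan and is excluded from GC numerator and denominator, so behaviour
on draft sequence is deterministic. Headline statistics follow the usual
definitions: coding percentage uses the *union* of CDS spans (overlapping
genes are not double counted) while mean CDS size uses the per-gene sum;
mean intergenic size averages the strictly positive gaps between
consecutive annotated features around the circle. Whether tRNA/rRNA
features should break intergenic runs is genuinely ambiguous in genome
tables of this kind; we compute gaps between *all* annotated features and
document that choice here.

## Pan-genome families

Ortholog families are built from all-vs-all local protein alignment
(Smith–Waterman, BLOSUM62, affine gaps open 11 / extend 1 — the de facto
protein-search defaults), keeping per query the single best-scoring subject
per genome direction above three floors:

* `min_identity = 30` (%) over the aligned region,
* `min_coverage = 0.5` of the shorter sequence,
* `min_score = 75` (raw alignment score).

The score floor deserves a note: identity and coverage floors alone admit
spurious 30–35% identity local alignments between *unrelated* proteins when
both are encoded under the same biased codon model (low-GC proteomes are
rich in I/K/N/L, and composition alone produces long mediocre alignments).
A raw score of 75 under this scoring scheme corresponds, via the
Karlin–Altschul statistics, to roughly the significance BLAST would demand
at these search-space sizes, and cleanly separates planted homologs
(scores ≥ 650 in the reference simulation) from compositional noise
(≤ 65). All four thresholds are ordinary arguments.

Reciprocal best hits (including within-genome self-pairs, which supply
paralog edges) form an undirected graph; families are its connected
components (single linkage), so total membership always equals the total
protein count. Categories: *ubiquitous* (≥ 1 member in every genome — the
core genome), *singleton* (one member in one genome), *shared* (the rest).
Multi-copy strain-confined families are placed in *shared* and flagged
(`multi_copy_single_genome`), since a strain-specific family with several
copies is not a singleton in the strict one-copy sense. Ties between equal
best scores break to the lexicographically smallest subject id, making
family construction order-invariant.

## CRISPR arrays

An array is a chain of near-identical direct repeats (20–50 bp) separated
by unique spacers. De novo detection is seed-driven: exact k-mers
(`seed_k = 12`) recurring with a period of 44–120 bp nominate a candidate
repeat; the repeat boundary grows around the seed while each column stays
≥ 75% conserved across the periodic copies; the refined consensus is then
handed to the repeat-driven scanner, which finds every Hamming match within
20% of the repeat length on both strands, discards overlapping matches
(best mismatch count wins), and clusters copies separated by at most the
anomalous-gap cap (2500 bp) into maximal arrays.

All mismatch handling is Hamming — no indels. This is deliberate: it keeps
every scan exactly equivalent to an exhaustive per-position oracle, which
the test suite exercises, and it matches how spacer/protospacer identity is
usually counted. Indel-tolerant matching is out of scope.

The anomalous-gap cap is the one knob that lets a kilobase-scale insertion
sit *inside* an array: two sub-arrays with the same consensus separated by
≤ 2500 bp merge into one array whose intervening segment becomes an
anomalous spacer. 2500 bp comfortably spans the ~1.9 kb pseudo-spacer class
of insertion while still splitting genuinely separate loci. Spacers longer
than 200 bp are flagged anomalous and reported with both flanking repeat
copies and their mismatch counts, so a pseudo-spacer can be shown to sit
between two *complete* repeats. Array orientation is reported `unknown`
unless the caller supplies leader evidence; orientation never affects
counts.

Protospacer matching scans both strands of every target and reports *every*
position within the mismatch budget (default 3 ≈ 92% identity on a ~38 bp
spacer), not only the best; `perfect` means zero mismatches. PAM inference
collects the 10 nt immediately 5' and 3' of each protospacer on the
protospacer strand (minus-strand hits are reverse-complemented first),
builds positional base-frequency matrices, and calls per position a single
base at frequency ≥ 0.7, a two-base call (e.g. `[T/A]`) when the top two
jointly reach 0.85 with the runner-up above 0.25, else no call. Flanks
truncated by target ends are skipped with a warning.

## Integrated elements

**Homolog windows.** Genes are annotated by best hit against a labelled
virus/plasmid protein database (same aligner and floors as above), then a
20 kb window is anchored at every annotated gene start; windows with ≥ 5
annotated genes are retained and overlapping retained windows merged.
Anchoring at hit genes only is provably equivalent to sliding the window
over every base pair — any per-bp window holding k hits can be slid right
until its left edge touches its first hit without losing any — and the
suite checks the equivalence against the exhaustive per-bp oracle.
Candidates are reported trimmed to their first and last hit gene.

**tRNA-linked elements.** Integrase-mediated integration duplicates an
attachment sequence at the tRNA 3' end, leaving direct repeats attL/attR
around the element. The scan anchors at the tRNA 3' terminus, searches the
downstream 50 kb (strand-aware) for a distal copy of the 3'-terminal
subsequence, working from 50 bp down to 15 bp at ≥ 80% identity, then
refines the att boundary to the anchored suffix maximizing identity
(longest on ties). Note the statistical limit here: a 15 bp att at 80%
identity is weak evidence in a 50 kb window (expected ≈ 0.6 chance hits per
tRNA); the identity floor and minimum length are arguments, and candidate
rows carry the att identity so callers can filter harder.

**Codon-usage clusters (CAG).** Per gene, codon frequencies over the 61
sense codons are compared with the genome-wide frequencies F by the
chi-square distance `d_g = sum_i (f_gi - F_i)^2 / F_i` (codons with
`F_i = 0` are skipped; genes under 30 codons are scored but flagged
low-confidence). Genes are ranked by `d_g` and cut into decile scores,
1 = most atypical tenth. A CAG is a maximal run of consecutive genes with
decile ≤ `max_score` containing at least one seed gene (decile ≤
`seed_score`), tolerating one interior interruption, with ≥ 5 member
genes. The shipped defaults are `max_score = 2`, `seed_score = 1`. A more
permissive ceiling is self-defeating: decile scores are by construction a
uniform partition, so a ceiling of 7 admits 70% of all genes and chance
runs of five appear throughout any genome whatsoever; restricting members
to the two most atypical deciles keeps the expected number of chance runs
far below one per genome while recovering every planted cluster exactly.

**IS elements and MITEs.** IS detection is library-driven: the consensus
termini (first/last 30 bp, 20% mismatches) are located on both strands and
paired within 0.3–1.2 of the consensus length, so internally deleted copies
are still anchored by their ends; the candidate is validated by a
gap-tolerant global alignment to the consensus (cheap gap extension — an
internal deletion must not destroy the identity estimate) and by the best
reverse-complement terminal repeat pair (ITR, ≥ 10 bp within 15%
mismatches, offsets ≤ 50 bp). The transposase is `intact` when the longest
internal ORF reaches 80% of the family reference ORF length, and a
truncated copy is `mobilizable_in_trans` when an intact same-family copy
exists elsewhere — the standard reasoning for counting potentially active
copies. MITEs are found either by class consensus (Hamming, ≥ 90%
identity) or de novo from structure alone: a terminal inverted repeat pair
spanning 50–400 bp, flanked by a target-site duplication, with no internal
ORF of ≥ 100 codons. The de novo seed is an exact TIR core of ≥ 12 bp with
a TSD of ≥ 3 bp: at the looser floors sometimes quoted for such scans
(TIR 10, TSD 2) the closed-form expectation on i.i.d. sequence is ≈ 2
false calls per 100 kb, so the shipped defaults sit one notch tighter and
land at ≈ 0.1–0.5 per 100 kb (compositional bias at 35% GC raises k-mer
coincidence rates above the uniform-composition estimate).

## Replication origins

The Z-curve components are cumulative disparities: `x = (A+G)-(C+T)`,
`y = (A+C)-(G+T)`, `z = (A+T)-(G+C)`; the ACCA plot is defined here as the
cumulative forward-minus-reverse strand bias of the tetramer ACCA (forward
ACCA occurrences minus forward TGGT, its reverse-strand image). That
definition is an interpretation — the historical method is not publicly
specified — and is documented as such. Curves are sampled every 100 bp,
smoothed by a 10 kb centred moving average; an extremum is a point that is
the maximum (or minimum) of the smoothed curve within ± 5 kb with strictly
lower (higher) values at both window ends, so monotone curves yield no
calls. Calls from different curves within 5 kb merge into one — the radius
only needs to unify co-located calls across curves, and a large radius
would chain distinct extrema together. Each call is linked to the nearest
candidate initiator gene (cdc6/whiP) within `link_cap` (10 kb by default;
the regression scenario uses 20 kb, matching its ± 20 kb recovery
tolerance) and labelled `oriC1..k` in call order. Origin-recognition-box
(ORB/nORB/UCM/C2/C3) consensus strings are plain inputs with per-motif
mismatch budgets; occurrences are reported on both strands with distances
to the nearest call.

## Exceptional words

Counts are overlapping, circular mode wraps the junction, and words
containing `N` are never counted. The default strand mode is forward-only
(a single deposited strand); both-strand counting is available. For a word
w of length l, the maximal-order (m = l-2) Markov expectation is

    E(w) = N(w[1..l-1]) * N(w[2..l]) / N(w[2..l-1]),

with the order-0 form for l = 2. The Gaussian variance uses the classical
maximal-order approximation
`V = E * (N(core)-N(prefix)) * (N(core)-N(suffix)) / N(core)^2`; Poisson
mode (`V = E`) is kept as a cross-check. Scores `z = (N-E)/sqrt(V)` are
ranked by |z|, ties broken by word. On i.i.d. sequence the scores are
calibrated (empirical mean ≈ 0, sd ≈ 1; the suite checks this over 20
seeds), which is what makes the ranking interpretable. The palindrome
report contrasts mean z of reverse-complement palindromes against other
words of the same (even) length — the avoidance signature expected from
restriction–modification carriers shows as a negative difference.

## Core-genome divergence and dating

Single-copy ubiquitous families supply the core alignment: equal-length
members are stacked directly (the simulator evolves by substitutions only,
so this is the common case); members within 20% length discordance are
globally aligned to the longest member (centre-star); families above that
are dropped with a message. Pairwise divergence is raw mismatch fraction
over pairwise non-gap columns by default — the clock calibration for
closely related hyperthermophile strains was made in a regime where raw and
corrected distances coincide — with Jukes–Cantor (`-3/4 log(1-4p/3)`,
undefined at p ≥ 0.75) available. Trees are standard neighbour-joining
(`ape::nj`); bootstrap resamples alignment columns and reports the fraction
of replicates recovering each bipartition, reproducible under a fixed seed.
Split dating uses `t = d / (2*mu)` with
`mu = 4.66e-9` substitutions/site/year — divergence accrues along both
descendant lineages; the per-lineage convention would halve t and is *not*
used. Recombination-aware genealogy inference is out of scope; NJ over the
concatenated core is the documented, weaker substitute.

## What the simulator emulates — and what it does not

`generate_background()` lays i.i.d. bases at the target GC with genes drawn
from a codon model consistent with that GC (codon probability proportional
to the product of base probabilities over sense codons), mean CDS 800 bp,
mean intergenic gap 190 bp — the architecture of a gene-dense 35% GC
archaeal chromosome. `plant_features()` inserts, at the intergenic gap
nearest each requested position: CRISPR arrays (exact repeat copies and
random 35–45 bp spacers, optionally one kilobase pseudo-spacer between two
complete repeats), viral/plasmid gene clusters whose translations populate
the labelled database, tRNA genes carrying att-delimited elements (the base
preceding each att copy is forced to differ so the realized duplication
length is exactly the planted one), IS copies (intact, internally deleted,
or ITR-destroyed) with a per-family consensus library, and MITE copies with
preserved TIRs, a TSD, and controlled identity. CAG clusters are planted by
re-encoding consecutive background genes under an extreme synonymous-
preference model (all mass on each amino acid's least-preferred codon),
preserving every protein exactly. Origins are planted by flipping, at each
origin and at the inter-origin midpoints, the direction of intergenic
C→G and A→T conversions (amplitude 0.9) and of planted ACCA/TGGT words —
gene bodies and planted elements are left untouched so their content
remains exactly as planted.

The reference scenario (`simulate_reference()`, 300 kb at GC 0.35) mirrors
the motivating chromosome's plastic architecture at one-eighth scale: five
CRISPR arrays of 86/113/31/25/30 spacers (285 in total; two share a
family-I 24 bp repeat, three a family-III repeat; the 113-spacer array
carries a 1.9 kb pseudo-spacer), four homolog-window elements of 6–13
genes, two tRNA elements with 22 bp att duplications, three IS copies and
four MITEs of two classes, three CAGs of 26/10/7 genes, and three origins.
Planted feature classes are spaced so that detectors do not interact: gene
clusters that hit the database sit > 20 kb apart (one scan window), and
CAG blocks sit well away from planted origins because a 10–30 kb block of
composition-shifted genes carries its own disparity trend of the same
order as a realistic skew signal. These spacing choices are the simulation
design, not detector tuning: each detector still sees the full genome.

What the simulator does **not** emulate: real repeat landscapes beyond the
planted features (no dispersed repeat families, no low-complexity tracts),
recombination and gene flux along the tree (substitutions only, so
coordinates stay comparable; an indel mode exists but is off by default),
degenerate repeat copies at array edges, nested elements, or the
taxonomic structure of real MGE databases. Green recovery tests therefore
demonstrate algorithmic correctness on clean instances, not performance on
real chromosomes, where diverged repeats, fragmented IS nests and
ambiguous att sites will dominate the error budget.

## Problem sizes and numerical choices

The regression suite runs the 300 kb reference scenario once per session
and shares it across tests; statistical checks use 100 kb null sequences
(20 seeds for word-score calibration), a 500 kb core over three replicate
pairs for divergence-time recovery (the mean estimate controls binomial
noise at the stated size), and a 400 kb background for the three-strain
dating example. These sizes were chosen so each quantity's sampling noise
is small against its tolerance. Determinism: every stochastic step takes
an explicit integer seed, derived seeds stay below 2^31, and emitting the
same scenario twice produces byte-identical files.

## Known limitations

* Protein search is exact Smith–Waterman without heuristics; proteome
  sizes in the hundreds are comfortable, whole 2500-gene proteome
  all-vs-all runs are slow in pure R — the hit-list contract accepts a
  drop-in external search backend producing the same record shape.
* De novo CRISPR detection assumes at least `min_copies` periodic exact
  12-mer seeds; arrays whose every copy is heavily degraded can be missed
  (the repeat-driven scanner with a known consensus is the fallback).
* Origin calling reports extrema of smoothed curves; composition islands
  (CAGs, GC-rich repeat arrays) produce genuine extra extrema, which stay
  unlabelled unless an initiator gene happens to sit nearby.
* The att scan's short-att regime is statistically weak (see above).
* Dating assumes a strict clock and raw distances; both are documented
  conventions, adequate for closely related strains only.
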