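---
title: "Methods and design of the t2tfinish toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the t2tfinish toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2tfinish)
```

`t2tfinish` packages the finishing computations that turn a good chromosome
assembly into a telomere-to-telomere (T2T) one, and the repeat-evolution
analyses that typically follow: telomere detection and read-based patching,
tandem rDNA (NOR) array reconstruction from unique 19-mers with k-mer-depth
copy-number estimation, organelle-contig screening, LTR retrotransposon
dating, centromere delineation, windowed identity matrices, and
cis-regulatory motif enrichment. Everything is exercised end to end on
synthetic genomes with exact feature truth, generated by the package itself.

This vignette explains the models and procedures, the parameters that
matter, what the simulator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## The synthetic-genome generator

A `genome_blueprint()` declares chromosomes and planted features;
`simulate_genome()` realizes it deterministically from a seed. The
background is i.i.d. uniform ACGT: the simplest null in which accidental
k-mer collisions are negligible at the k = 19-31 sizes the toolkit uses
(probability per pair of positions `4^-19`), so every planted repeat
structure is the *only* repeat structure.

Planted features:

* **Telomeres** - tandem (TTTAGGG)n arrays at both ends, with a configurable
  fraction of copies drawn as the one-substitution TTCAGGG variant (default
  5%). The right end carries the forward motif, the left end its reverse
  complement, making the genome self-consistent under reverse complement.
* **An NOR** - `copies` tandem rDNA units placed directly after the left
  telomere, as on an acrocentric NOR arm. Units come in two length classes
  (defaults 8,351-8,377 bp and 8,498-8,506 bp at 70/30), realized as
  prefixes of a single maximum-length unit consensus. Each unit carries
  private interior substitutions at 0.2%/site, kept >= 100 bp away from unit
  boundaries. The divergence level is the realistic part: real rDNA arrays
  are homogenized but not identical, and that low intra-array divergence is
  exactly what makes rare-k-mer anchoring possible - a literally identical
  array has no unique 19-mers and cannot be reconstructed by any
  unique-k-mer method. The boundary margin is a simplification that makes
  k-mer-coverage trimming of the reconstructed array exact at the ends.
* **LTR retrotransposons** - per clade, an LTR consensus (1 kb) and internal
  consensus (4 kb); intact elements are LTR-internal-LTR with the two LTRs
  mutated independently along branches of length K/2 (per-site substitution
  probability `3/4(1 - exp(-2K/3))`, the Jukes-Cantor inverse), so their
  expected divergence is the target K; solo LTRs are single copies at branch
  K/2. Realized divergences are recorded in the truth table.
* **A centromere** - an interval filled with CRM-clade Gypsy elements,
  distributed one per equal-width slot until the requested bp density
  (default 0.3) is reached, with their own (younger) K and (lower) solo
  fraction. The same interval drives ChIP-track enrichment.
* **Organelle material** - a simulated organelle genome plus nuclear
  insertions copied from it at random positions.

Reads (`simulate_reads()`) follow two regimes: `hifi_like` (normal lengths,
18 +/- 4.5 kb, 0.1% substitutions, no indels) and `ont_like` (lognormal
lengths around 30 kb with a long tail, 3% substitutions, 1% indels) - the
short-accurate versus long-noisy contrast of real HiFi and ONT ultralong
data, scaled to desk size. Read names encode the true origin
(`chrom:start-end:strand`, 0-based half-open), so recall and precision are
computable without alignment. ChIP tracks (`simulate_chip_track()`) draw
Poisson window counts with the IP mean multiplied by the enrichment factor
inside planted centromeres.

What the simulator does **not** emulate: genome-scale repeat landscapes
(real pepper genomes are ~80% repetitive; here repeats exist only where
planted), nested/fragmented TE insertions, satellite arrays, sequence
context effects on errors, chimeric reads, heterozygosity and polyploidy,
and chromatin realism beyond a flat Poisson background. Passing tests
therefore demonstrate the *correctness of the computations* under known
truth, not their robustness to every pathology of real data; on real data
the anchoring steps face repeat-induced ambiguity that here appears only in
the controlled forms planted by the generator.

Coordinates are 0-based half-open (BED convention) everywhere: truth tables,
calls, reports.

## Telomere detection and patching

`scan_terminal_telomere()` searches the terminal window (default 20 kb) of
each contig for tandem runs of the 7-bp motifs, using all 7 rotations of
each motif so the register at which an assembly truncates the array is
irrelevant. Copy count is a greedy maximal non-overlapping placement;
purity is motif bases over run span. Assembly-level calls require 100
copies (assembled telomeres carry thousands; 100 cleanly separates true
arrays from stray motifs in ~20 kb of sequence, where the expected count of
chance 7-mer matches is far below one run of that size) and purity 0.8.
This scanner replaces general tandem-repeat finders: for a fixed 7-mer
family an exact rotation scan is complete, dependency-free and faster.

Read selection uses the ultralong-read thresholds: length strictly greater
than 200 kb and at least 10 tandem copies of a motif or its reverse
complement.

`anchor_read_to_end()` places a read against a contig end using k-mers
(k = 21) that are unique within the terminal 50 kb window, clustering seed
diagonals with 100 bp tolerance (absorbs small indels) and accepting the
placement with the most seeds if it has at least 20. In random background,
a single shared unique 21-mer is already near-conclusive; 20 collinear
seeds make false anchors vanishingly unlikely while tolerating real ONT
error rates. `patch_telomere()` then appends the overhang of the
best-ranked anchor (most seeds, then longest overhang, then lexicographic
read id - a deterministic total order) after verifying that all supporting
overhangs agree pairwise to >= 90% identity over their terminus-aligned
overlap; disagreement is a conflict error and nothing is patched. Patching
appends only: the input contig is always a contiguous substring of the
output. Default support is a single read, mirroring manual single-read
patching practice; the conflict check is the guard rail that manual
inspection would otherwise provide.

## rDNA array reconstruction and copy number

Copy number is k-mer mass over depth: `estimate_copy_number(M, d) =
floor(M/d)`. Floor, not round: the worked division 60,000/42 = 1,428.57
must print 1,428. The mass `M` is defined operationally by
`measure_kmer_mass()` as the **median** total multiplicity, over the
unit-internal canonical 19-mers of the consensus, in the unit-containing
read set - a robust statistic that ignores flanking sequence in boundary
reads and is linear in read multiplicity. When `M` and `d` are supplied
directly the function reproduces the plain division.

Reconstruction follows the unique-k-mer anchoring idea. Reads are selected
by unit k-mer content (>= 20% of a read's canonical 19-mers in the unit
set), oriented to the unit strand, and classified: *prefix* reads carry a
telomeric run, *internal* reads are unit sequence at both terminal 2-kb
windows (>= 80% unit k-mers), *suffix* reads run off the array (one window
< 20%). `build_array_graph()` keeps k-mers that occur exactly once in every
fragment containing them and at most `rare_max_read_mult` times in the read
set; fragments sharing rare k-mers become edges annotated with the modal
implied offset (consistent if >= 80% of shared k-mers agree).

Numerical choices worth recording:

* The multiplicity cutoff must sit **between** local coverage excursions
  and the 2x-depth multiplicity of k-mers duplicated across array
  positions. Long reads make coverage locally autocorrelated - 30-kb reads
  at 10x mean routinely produce 20-kb stretches at 17x - so a cutoff at
  1.5x depth can delete every unique k-mer of a whole region and
  disconnect the graph. The pipeline uses 2.5x depth.
* Layout is a maximum-weight spanning construction: edges are processed by
  descending k-mer support through a union-find that carries coordinates,
  so the heaviest (most trustworthy) evidence fixes the layout first. An
  edge that contradicts the established layout is either repeat noise
  (duplicated unit junctions can muster at most a few dozen supporting
  k-mers; dropped) or a genuine ambiguity (>= 60 supporting k-mers; error
  naming both fragments). After layout, every overlapping base between
  placed fragments is verified - a planted bifurcation fails here with an
  ambiguity error rather than a silent tie-break. Ambiguity-as-error is
  deliberate: the cases a real project resolves with orthogonal data
  (Hi-C) are out of scope, and guessing would be worse than stopping.
* The merged sequence is trimmed to the span covered by exact consensus
  19-mers and the copy count is the number of unit-start anchor matches
  within it. On zero-error reads the result is bit-identical to the planted
  array.

`fill_array_gaps()` closes N-runs whose flanking 19-mers are unique in the
draft, splicing in the subsequence of a read containing both flanks (either
strand); gaps with no spanning read are reported, not guessed.

## Organelle screening and nuclear insertions

A contig's organelle coverage fraction is the interval union of exact
canonical 31-mer matches against the organelle references (each match
covering its 31 bases) divided by contig length - the same covered-base
quantity a collinear-chaining implementation reports, computed directly.
31-mers rather than 19: discriminating organelle from nuclear sequence
wants longer seeds than intra-array anchoring. Removal applies at fraction
>= 0.5 - *at least half* is inclusive - and is idempotent on the kept set.
One caveat of exact matching: a reported boundary can extend up to k-1 bp
past the true junction when the adjacent nuclear base happens to continue
an organelle k-mer, so boundaries are exact only up to that coincidence.

Nuclear insertion candidates are maximal organelle-matching intervals (hits
merged across <= 200 bp gaps) with >= 5 kb of non-organelle sequence on both
sides; a candidate is *supported* only if some read anchors with one
consistent seed diagonal in **both** flanking windows, i.e. spans the whole
integration site - the read-based criterion that distinguishes a real
nuclear insertion from organelle contamination mapping on top of the
assembly.

## LTR chronology

Divergence between the two LTRs of an intact element comes from a global
affine-gap alignment (match +1, mismatch -2, gap open -4, extend -1);
p is mismatches over aligned non-gap columns and the default Jukes-Cantor
correction `K = -(3/4) ln(1 - 4p/3)` (raw p behind a flag) keeps dating
consistent at higher divergences; p >= 0.75 is a saturation error.
Insertion time is `T = K/(2r)` with r = 7e-9 substitutions/site/year, the
standard average substitution rate for these genomes: each LTR accumulates
substitutions independently after insertion, so the pair diverges at 2r per
year. At K = 0.0546 this gives 3.9 Myr, the age scale of the older LTR
amplification bursts in cultivated pepper genomes.

At 2-kb LTRs the binomial sampling noise of p sets a floor on dating
precision: at K = 0.01 the relative standard error is ~22%, falling to ~7%
at K = 0.05. Accuracy statements about the estimator are therefore made on
element *sets* (mean absolute relative error over 300 simulated elements is
~10%), not on single young elements.

Solo:intact ratios assign elements to regions by midpoint (unambiguous for
boundary-straddling elements); a region with zero intact elements reports
NA with a warning, never infinity. Distribution comparisons use the
two-sided Wilcoxon rank-sum test - exact for tie-free samples of at most
20, otherwise the tie-corrected normal approximation with continuity
correction - reporting medians and quartiles alongside, since those are
what the distributions are summarized by.

## Centromere delineation and identity matrices

`windowed_enrichment()` aggregates IP and input bedGraph tracks into
tiling windows (default 30 kb), scales each library to the mean total
count, and forms `(ip + 1)/(input + 1)`. Total-count scaling is the
simplest normalization consistent with ratio tracks; note it slightly
deflates the observed ratio below the true enrichment factor when the
enriched fraction of the genome is non-negligible, which is why the caller
thresholds well below the simulated factor. Calling seeds windows at ratio
>= 2, merges seed runs across at most 3 sub-threshold windows, and drops
calls shorter than 300 kb; the same machinery calls centromeres from CRM
bp-density (threshold 0.2 bp/bp) when no ChIP data exist. These three
defaults automate what is otherwise a by-eye boundary decision on an
enrichment track; all are exposed as arguments and recorded in outputs.
One call per chromosome is the expectation; extras are flagged rather than
silently dropped.

`identity_matrix()` cuts a region into non-overlapping windows (default
5 kb, trailing partial dropped) and computes percent identity between every
pair from a full global alignment - exact, and at desk scale there is no
need for the banded approximation that genome-wide implementations use.
The diagonal is exactly 100; symmetry holds to within alignment asymmetry
(<= 0.5 points). `tidy()` and `autoplot()` give the long table and heatmap.

## Motif enrichment

`scan_motifs()` does IUPAC-aware exact matching on both strands; N in a
*sequence* never matches (sequences are scanned as their N-free segments),
and a palindromic consensus is counted once per site. The shipped library
covers the five classic plant cis-element families (MYB, G-box, Box-4,
ABRE, MYC) as editable consensus strings; position weight matrices are out
of scope. Note the MYC E-box CANNTG is deliberately degenerate and
saturates long background sequences - in enrichment designs the sequence
length matters as much as the counts.

Enrichment is a one-sided exact hypergeometric test on the 2x2
presence/absence table (the simplest defensible statistic when none is
prescribed; an occurrence-count binomial test is available behind a flag),
with BH q-values always reported alongside and the enrichment call made on
raw p < 0.01. The exact test is conservative: on 500 null replicates the
realized type-I rate is below the nominal 1% (around 0.5%), comfortably
inside the binomial interval expected from 500 replicates, and power
against a 90% vs 10% presence contrast at n = 50 is essentially 1. When no
background is supplied, `shuffle_background()` provides a seeded
first-order Markov resample of the foreground, preserving dinucleotide
composition in expectation (a pragmatic stand-in for an exact
dinucleotide-preserving Euler shuffle).

`intersect_enriched()` returns the motifs enriched in both of two analyses
(e.g. open-chromatin regions and 2-kb upstream sequences), ordered by the
larger of the two p-values.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run everything on seeded
synthetic material sized for a desktop: 0.6-3 Mb chromosomes, a 50-copy
(~420 kb) NOR at 10x zero-error coverage, 300 simulated LTR pairs, 500
null and 200 power replicates for the motif statistics. These sizes are
large enough that every statistical check has the resolution its tolerance
requires, and small enough that the full suite runs in minutes. All
randomness flows through explicit seeds; rerunning any pipeline with the
same blueprint and seed reproduces outputs byte-for-byte.

Known limitations: the rDNA reconstructor requires per-unit sequence
variation (it reports failure, not a guess, on a perfectly homogeneous
array, where the problem is information-theoretically unsolvable by unique
k-mers); anchoring steps assume error rates low enough that 21-mer seeds
survive (~0.95^21 of seeds at 3% error - ONT-like data works, but raw
high-error reads would not); organelle screening is exact-match based and
will under-report diverged ancient insertions; and the centromere callers
inherit the windowed resolution of their inputs (boundaries are only ever
window-precise).
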