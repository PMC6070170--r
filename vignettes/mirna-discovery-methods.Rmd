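---
title: "Methods: homology-based plant miRNA discovery with plantmir"
author: "plantmir maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based plant miRNA discovery with plantmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantmir)
```

## The problem and the model

Mature plant miRNAs (~17–25 nt) are conserved across wide evolutionary
distances, while their precursor hairpins diverge. In species without
an assembled genome, conserved miRNAs can therefore be recovered from
transcriptome assemblies by homology: find transcript loci nearly
identical to a known mature miRNA, excise a window around each locus,
and ask whether that window folds into a pre-miRNA-like stem-loop.
Because any short sequence will match somewhere by chance, the
discriminative power is in the structural filter, not the scan.

`plantmir` operationalizes the classical criterion set:

1. the candidate folds into a single stem-loop;
2. the miRNA:miRNA\* duplex is defined (the mature does not straddle
   the terminal loop) and carries fewer than 6 mismatches — a
   *mismatch* being a mature position with no pairing partner; G:U
   wobble counts as paired, consistent with plant miRNA practice;
3. the mature lies wholly on the 5p or the 3p arm;
4. MFEI ≤ −0.49;
5. MFE ≤ −15 kcal/mol;
6. no bulge in the duplex longer than 3 nt and no internal-loop
   asymmetry above 2 nt;
7. G+C content between 24 % and 71 %;

plus precursor length 60–400 nt, mature length 17–25 nt, and at least
16 paired mature positions. The composite statistics are
AMFE = 100·MFE/LP and MFEI = AMFE/GC%; MFEI is the workhorse
discriminator because genuine precursors fold more stably per
nucleotide than other RNAs of the same composition.

The wording of criterion 6 in the originating literature is
self-contradictory ("3 nt asymmetric bulge … not more than
2 nucleotides"); we resolve it as *bulge run ≤ 3 nt and per-loop
asymmetry ≤ 2 nt*, both configurable. Criterion 4's "higher negative
MFEI than other RNA species" is pinned to −0.49, the least negative
value accepted in the published survey bundled with the package; much
of the literature uses −0.85, so `filter_criteria(max_mfei = )` exposes
it.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `max_mismatches` | 2 | nt | conserved-mature scan tolerance |
| `flank` | 150 | nt | window half-width around a hit |
| `seed_word` | 28 | nt | exact seed for known-precursor screening |
| `min_precursor_identity` | 0.90 | – | ungapped identity screen |
| `max_mfe` | −15 | kcal/mol | minimal hairpin stability |
| `max_mfei` | −0.49 | – | precursor-vs-other-RNA discriminator |
| `gc_min`, `gc_max` | 24, 71 | % | composition plausibility window |
| `max_bulge`, `max_asymmetry` | 3, 2 | nt | duplex geometry |
| `min_duplex_pairs` | 16 | nt | minimal mature:star pairing |
| cluster `max_gap` | unlimited | nt | one polycistron = one cluster |
| target `cutoff` | 5.0 | – | complementarity penalty ceiling |

The target-prediction cutoff of 5.0 is a documented assumption: it is
the conventional default of plant target-prediction servers, and the
originating study does not state the value it used.

## Design choices where the design was open

**Coordinates.** The in-memory API is 1-based closed, the R/Bioconductor
(IRanges) convention, because every consumer of these results in R will
compose them with IRanges-style tooling. BED-like region files on disk
stay 0-based half-open and are converted on read/write.

**Replacing BLASTn.** For 17–25 nt queries at ≤ 2 mismatches, an
exhaustive full-length Hamming scan over every window of both strands
is a superset of what a word-7 seeded BLAST can report, is
deterministic, and removes an external binary. The BLAST e-value plays
no role in the decision rule and is dropped. The precursor screen is
ungapped seed-and-extend; indel-containing loci are missed by
construction (a documented limitation — the 90 % rule is a screen, not
an alignment).

**The bundled folding model.** `fold()` minimizes an additive per-pair
energy (GC −3, AU −2, GU −1 kcal/mol, loops ≥ 3 nt) by an O(n³)
interval dynamic program with a fully specified traceback (pairing
preferred over bifurcation, leftmost optimal split), so output is
bit-stable. This is a weighted Nussinov model, *not* nearest-neighbour
thermodynamics: its MFE values are internally consistent and
brute-force-verifiable (the test suite checks it against exhaustive
enumeration of all nested structures for short sequences), but they do
not reproduce Mfold/ViennaRNA energies. All filter logic is
energy-source-agnostic; `fold(seq, model)` accepts any function
returning `list(dotbracket, energy)`, so a thermodynamic backend can be
swapped in without touching the filter. Consequently the published
per-precursor MFE values are treated as *inputs* wherever they matter
(the MFEI arithmetic), never as quantities to reproduce.

**Trimming before evaluation.** After folding the ±150 nt window, the
pipeline trims the candidate to the outermost base pair enclosing the
mature site and refolds. Published precursor tables report trimmed
precursors (tens of nt, not 300), and without trimming the unpaired
window flanks dilute AMFE — a 320-nt window around a ~45-bp stem has
MFEI ≈ −0.33 under the bundled weights, below any sensible threshold,
regardless of how good the hairpin is. Trimming is on by default and
configurable (`pipeline_config(trim = FALSE)`).

**Deduplication.** Overlapping accepted candidates on one transcript
collapse to the best (most negative) MFEI, then the leftmost: one
locus, one precursor call. Deduplication happens after filtering, so
the rejected table still accounts for every evaluated hit.

**Clusters.** The literature never defines "cluster" by a fixed
distance; the default `max_gap = Inf` groups all accepted precursors on
one transcript unit, matching how a polycistronic pre-rRNA carries its
miRNAs, and a finite gap is available for genomic use. Region labels
use the span midpoint, with a boundary flag whenever a span straddles a
region edge, so the single deterministic label loses no information.

**Expression.** Replicates are averaged on the Ct scale before
2^−ΔΔCt (standard Livak practice; the efficiency-corrected Pfaffl
model is out of scope), and the calibrator tissue is a required
argument because published designs calibrate on different tissues per
experiment. Published fold-change values are not reproducible from the
outside — their input Ct values are not printed — so the package's
tests assert the arithmetic identities (calibrator ≡ 1, shift
invariance, log2 linearity) instead.

## What the synthetic generator emulates — and what it does not

`make_transcriptome()` and `make_pre_rrna()` produce the statistical
structure the analysis assumes: transcripts carrying foldable precursor
hairpins around known mature sequences, decoy loci violating individual
criteria, random background transcripts (uniform composition,
300–2000 nt), and one long annotated polycistron with three precursors
planted in its "18S" region and two in "28S", mirroring a five-miRNA
pre-rRNA cluster.

Planted precursors are built as
`[tail][ext + mature + ext'][loop][star][tail]`, where the star arm is
the reverse complement of the mature-bearing arm carrying 0–6
single-base *deletions* opposite the mature interior. Three deliberate
artificialities make the designed fold the provable energy optimum
under the bundled model:

- unpaired filler (loops, tails, spacers) is poly-A or {A,C}, which
  cannot base-pair internally under canonical or wobble rules;
- both stem ends carry 3-bp G:C clamps, so trading an edge pair (−3)
  for any filler pairing (at best −2) always loses;
- star mutations are deletions, which add no pairing capacity (a
  substitution could pair elsewhere and reshape the optimum).

Even so, equal-energy gap *placements* exist whenever the mature's own
repeat structure makes "delete sites {a,b,c}" string-equivalent to
deleting a different site set; the deterministic traceback then
realizes one canonical placement, which can merge gaps into an
over-long bulge. Generators therefore verify every planted precursor
through `evaluate_candidate()` — untrimmed and trimmed — at generation
time and deterministically retry with derived seeds until the truth
record holds; decoys are likewise verified to fail their designated
criterion. All generation is a pure function of the arguments and the
seed.

What a green test on this world establishes: the scan, window, fold,
trim, filter, deduplication and cluster stages are correct against
known truth. What it does not establish: recovery rates on real
transcriptome assemblies (no sequencing error, no assembly artifacts,
no paralogous families, uniform background composition), nor
thermodynamic realism of the energies, nor the behaviour of the 90 %
precursor screen under indels.

## Numerical conventions and degenerate inputs

- Reported statistics are rounded half-away-from-zero to 2 dp; tests
  against the bundled published table accept ±0.015 at 2 dp because
  printed tables mix rounding and truncation. Rows of the bundled
  survey whose printed MFEI does not follow from their own MFE/LP/GC
  columns are *flagged* by `annotate_mfei()` (three rows), never
  forced.
- `N` is kept through IO, never matches in scans, and is unpairable in
  folds; all other IUPAC ambiguity codes are rejected because the
  filters are base-exact.
- Ties: the scan reports hits in coordinate order; `locate_mature`
  prefers fewest mismatches then leftmost; traceback prefers pairing
  over bifurcation and the leftmost optimal split; deduplication
  prefers best MFEI then leftmost.
- Degenerate inputs are verdicts, not crashes: an unfoldable window
  fails the structural criteria; an empty transcriptome yields an
  all-zero run summary; a mature outside 17–25 nt is skipped with a
  warning.

## Known limitations

- The bundled energies are not thermodynamic; absolute MFE/MFEI values
  from the bundled model are comparable only within a run (plug in a
  thermodynamic backend for publishable energies).
- The precursor screen is ungapped.
- `arm_of` reports `ambiguous` for any structure without exactly one
  terminal loop; no attempt is made to resolve arms inside multi-loop
  folds.
- Target scoring is ungapped and site-length-bound; bulged target sites
  are not modelled.
```{r session}
sessionInfo()
```
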