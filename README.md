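# plantmir

Homology-based discovery of conserved plant microRNAs from
transcriptome assemblies.

Mature plant miRNAs are strongly conserved across species while their
precursors are not, so a classical way to annotate miRNAs in a species
without a reference genome is to scan its assembled transcripts for
near-exact copies of known mature miRNAs, fold the surrounding sequence,
and keep only loci whose structure looks like a genuine pre-miRNA
hairpin. `plantmir` implements that whole in-silico pipeline as a
tested, dependency-light R package:

- **Homology scan** — an exhaustive, deterministic Hamming scan of every
  transcript window (both strands) against each mature query, allowing
  0–2 mismatches for 17–25 nt queries; a seed-and-extend screen
  (exact 28-mers, ≥ 90 % identity) for known precursors. For these
  query sizes the exhaustive scan finds a superset of what a word-7
  BLASTn can find, with no external dependency.
- **Window extraction and folding** — ±150 nt around each hit, folded by
  a bundled weighted-pairing dynamic program (GC −3, AU −2, GU −1
  kcal/mol, hairpin loops ≥ 3 nt) with a fully deterministic traceback;
  external thermodynamic folders can be plugged in behind the same
  `sequence → (dot-bracket, energy)` contract.
- **Seven-criterion filter** — single stem-loop; defined miRNA:miRNA\*
  duplex with < 6 mismatches and ≥ 16 pairs; mature wholly on the 5p or
  3p arm; MFEI ≤ −0.49; MFE ≤ −15 kcal/mol; bulges ≤ 3 nt with
  internal-loop asymmetry ≤ 2 nt; G+C between 24 % and 71 %; precursor
  length 60–400 nt. The key statistics are

  ```
  AMFE = 100 · MFE / LP          (kcal/mol per 100 nt)
  MFEI = AMFE / GC%
  ```

  where LP is the precursor length. MFEI separates miRNA precursors
  from tRNA/rRNA/mRNA, which fold less stably per nucleotide at the
  same base composition.
- **Cluster detection** — accepted precursors co-located on one
  transcript unit (e.g. a polycistronic pre-rRNA) are grouped into
  clusters and labelled with annotated regions
  (ETS/18S/ITS1/5.8S/ITS2/28S) by a midpoint rule.
- **Target scoring** — a standard plant complementarity penalty scheme
  (mismatch 1, G:U wobble 0.5, doubled at positions 2–13; cleavage vs
  translational mode by central pairing).
- **Expression arithmetic** — Livak 2^−ΔΔCt relative quantification and
  reference-normalized band densitometry.
- **Synthetic data** — seeded generators for ground-truthed
  transcriptomes: plantable precursor hairpins around any mature
  sequence, decoys that each violate one designated criterion, and an
  annotated synthetic pre-rRNA carrying a planted five-miRNA cluster.
  Every stage of the pipeline is testable offline.

A bundled reference table (`papaver_mirna_table()`) carries the printed
per-precursor statistics (A+U %, G+C %, LP, MFE, MFEI) of a published
survey of 22 conserved miRNAs in *Papaver somniferum* and
*P. bracteatum*, used for arithmetic cross-checks and as realistic
mature queries.

## Worked example

```r
library(plantmir)

tab <- papaver_mirna_table()

# MFEI from a published row: MFE -62.80, LP 95, GC 72.63%
round(compute_mfei(-62.80, 95, 72.63), 2)
#> [1] -0.91

# a synthetic transcriptome: 20 background transcripts, 3 planted
# precursors around real mature sequences, 2 criterion-specific decoys
planted <- setNames(tab$mature_sequence[1:3], tab$name[1:3])
syn <- make_transcriptome(n_background = 20, planted = planted,
                          decoy_specs = c("vii", "ii"), seed = 7)

res <- run_pipeline(pipeline_config(matures = syn$queries,
                                    transcriptome = syn$sequences,
                                    seed = 7))
res$accepted[, c("query_id", "lp", "gc_percent", "mfe", "amfe", "mfei", "arm")]
#>      query_id lp gc_percent  mfe    amfe  mfei arm
#> 1 pso-miR1310 97      57.73 -115 -118.56 -2.05  5p
#> 2 pso-miR2910 93      45.16 -104 -111.83 -2.48  5p
#> 3 pso-miR2911 91      61.54 -109 -119.78 -1.95  3p

res$rejected[, c("query_id", "failed")]
#>           query_id                               failed
#> 1 decoy_vii_01_mat i_single_hairpin,...,vii_gc,...
#> 2  decoy_ii_02_mat                 ii_duplex_mismatches
```

All three planted precursors are recovered with the correct arm; both
decoys are rejected and the rejection names the criterion each decoy
was built to violate (`vii_gc`: G+C out of range; `ii_duplex_mismatches`:
too many unpaired mature positions). LP/MFE/MFEI here come from the
bundled additive folding model, so they are internally consistent but
are not nearest-neighbour thermodynamic energies (see the vignette).

The structural analogue of a clustered polycistron:

```r
rr <- make_pre_rrna(seed = 1)   # 3 precursors in "18S", 2 in "28S"
res <- run_pipeline(pipeline_config(matures = rr$queries,
                                    transcriptome = rr$reference,
                                    regions = rr$regions))
res$clusters[, c("id", "start", "end", "size", "region")]
# one cluster of five, labelled 18S/18S/18S/28S/28S
```

## Acceptance script

`scripts/acceptance.R` recomputes, from the installed package and the
bundled published table, the MFEI values of four reference precursor
rows and the minimum recomputed MFEI across all 22 rows, and writes
them as JSON. It also runs the full synthetic discovery pipeline once
as an end-to-end sanity check.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                 sequence IO, homology scan, folding, filter,
                   clusters, targets, expression, generators, pipeline
src/nussinov.cpp   the O(n^3) folding dynamic program
inst/extdata/      bundled published precursor table (TSV)
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette
```
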