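---
title: "Detecting prophages by density-based clustering of phage-homologous genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prophages by density-based clustering of phage-homologous genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The detection model

Prophages are phage genomes integrated into a bacterial chromosome. Because
they arrive by a single insertion event, their genes sit in one contiguous
block, and because they arrive from a different genome, the block often
carries two compositional footprints: a G+C content that deviates from the
host baseline, and a transfer-RNA gene at the insertion boundary (tRNA loci
are preferred integration sites).

`prophagescan` turns these observations into a pipeline:

1. **Homology.** Each CDS of the annotated genome is searched against a
   phage protein collection (any protein FASTA; DIAMOND or BLAST+ if
   available, or a precomputed 12-column tabular hits file). Hits are kept
   when the alignment identity reaches `min_identity` (default 80%, the
   setting under which the approach was benchmarked) and the e-value is at
   most `max_evalue` (default 1e-5, a conventional cutoff; the identity
   threshold is the primary filter). One best hit per CDS is retained so
   that each gene has a single candidate source phage.
2. **Clustering.** The genomic *midpoints* of phage-homologous genes are
   clustered in one dimension. A true prophage produces a dense run of
   midpoints; scattered spurious hits do not. The production algorithm is
   HDBSCAN\*; DBSCAN and OPTICS are available for comparison, and all three
   share the `min_pts` parameter (MinPts): the minimum number of
   phage-homologous genes a region must contain.
3. **Evidence (optional, annotative).** Each candidate region is scored for
   G+C deviation and flanking tRNAs. Evidence never removes a region —
   regions failing both checks are reported with their flags set to FALSE,
   leaving the judgement to the user.
4. **Conservation.** A region whose genes mostly derive from one source
   phage is more likely an intact (rather than decayed or mosaic) element.
   With the best-hit assignment, a region is called *potentially conserved*
   when at least `conservation_threshold` (default 0.80) of its member
   genes best-hit the same phage; genes without any surviving hit stay in
   the denominator, since excluding them would inflate the fraction.

## Why the clustering feature is the 1-D midpoint

Only the genomic coordinates of the homologous genes carry the positional
signal; strand and gene length do not. The midpoint is symmetric in both,
and one-dimensional clustering makes every algorithmic step exact: core
distances are order statistics of absolute differences, and the minimum
spanning tree of the mutual-reachability graph is computed exactly.

## HDBSCAN* as implemented here

The implementation follows the HDBSCAN\* construction: the core distance of
a point is the distance to its `min_pts`-th nearest neighbour (the point
itself counted first); the mutual reachability of two points is the maximum
of their core distances and their distance; a minimum spanning tree of the
mutual-reachability graph is condensed into a cluster tree with
`min_cluster_size = min_pts`, and clusters are selected by excess of mass.
Mapping MinPts to *both* `min_samples` and `min_cluster_size` matches its
reading as "minimum number of phage proteins in a region". Defaults:

* `min_pts = 4` — the smallest defensible phage cassette; fully
  user-configurable, and deliberately a first-class parameter of the tool.
* `allow_single_cluster = TRUE` — a deliberate departure from the common
  library default. Excess-of-mass selection normally bars the hierarchy
  root, so a genome whose phage-like genes form one single dense block (one
  prophage, no noise hits) would return nothing. For this application that
  is the wrong answer, so the root is eligible by default. The
  cross-checks against an external HDBSCAN reference pass the flag
  explicitly on both sides.

Determinism is guaranteed throughout: points are processed in coordinate
order, equal distances resolve by index (= coordinate order), and final
labels are renumbered `0..k-1` by each cluster's leftmost member. Zero
distances (coincident midpoints) clamp the corresponding density level
rather than overflowing. Circular genomes are clustered as linear; a
cluster split across the origin is not merged.

DBSCAN uses an exact sorted-coordinate implementation (neighbour counts by
binary search; border points join the cluster of a core neighbour,
preferring the left one, which reproduces the left-to-right seed-expansion
order of the textbook algorithm). A brute-force O(n²) density-reachability
oracle, `dbscan_1d_oracle()`, ships in the package as the independent
reference for tests. OPTICS computes the standard reachability ordering and
extracts DBSCAN-equivalent clusters at the cut radius `eps`
(default 10 000 bp for both algorithms; HDBSCAN\* needs no radius).

## The G+C rule

A sliding window of `gc_window` bp (default 1000) advances in steps of
`gc_step` bp (default 100; the construction only states that the window
slides, and 100 bp balances resolution against cost) from position 1 while
the window fits. The mean and *population* standard deviation of the window
G+C values form the genome baseline — population SD because the windows
enumerate the genome rather than sample it. A member gene is *deviant* when
the G+C fraction of its genomic span (strand-independent, as G+C content is
invariant under reverse complement) lies strictly above mean + SD or
strictly below mean − SD; the region is G+C-supported when at least
`gc_gene_fraction` (default 0.80, boundary inclusive — "at least 80%") of
its genes are deviant. The strictness sits where the wording puts it: strict
at the per-gene deviation, inclusive at the 80% aggregation. Window
statistics (not per-gene statistics) define the baseline, since the sliding
window is what the construction defines. Ambiguous bases are excluded from
both numerator and denominator of every G+C fraction.

One behaviour worth knowing: the baseline mean and SD are computed over the
*whole* genome, prophages included. When implants make up a large share of
the sequence (as in compact simulated genomes), they inflate the SD and can
mute their own signal. On real chromosomes (prophages are typically a few
percent of the sequence) the effect is small.

## tRNA flank evidence

A region is tRNA-supported when at least one tRNA feature lies inside it or
within `flank_distance` bp (default 2000) of either boundary. "Flanking" is
nowhere quantified in the underlying method; 2 kb is a deliberately
generous, configurable default, and each qualifying tRNA is reported with a
signed distance (negative upstream of the start, positive downstream of the
end, 0 inside) so stricter post-filtering is trivial.

## Evaluation machinery

`match_regions()` computes sensitivity Sn = detected references / total
references and positive predictive value PPV = detected / (detected +
predictions overlapping no reference). The default detection rule is
*any overlap* (≥ 1 bp), the weakest defensible reading of "detected";
`min_fraction` is exposed for stricter studies. Many-to-one matches count a
reference once.

The four cluster validity indices (Silhouette, Dunn, Davies–Bouldin, DBCV)
are implemented from their defining formulas and verified in the test suite
against independent brute-force evaluations to 1e-9. Noise points are
excluded from all four, including DBCV's cluster-size weights — a
documented convention, since the published DBCV weights clusters by their
share of *all* points. DBCV's dimension term is 1 (the data are 1-D).
Two numerical conventions make DBCV single-valued: mutual-reachability ties
are resolved by the strict total edge order (weight, then index pair), so
the per-cluster minimum spanning tree is canonical; and a cluster with no
internal MST node falls back to all nodes. A zero Dunn denominator
(coincident points) returns +Inf, documented rather than an error.

## What the synthetic generator emulates — and what it does not

`generate_genome()` builds the study conditions the package is tested
under: a background chromosome of i.i.d. nucleotides at `background_gc`
(default 0.45), `n_prophages` (default 3) non-overlapping implants of
15–45 kb (the span range of curated prophages in bacterial chromosomes)
shifted by `prophage_gc_shift` (default +0.10), 10–30 genes tiled per
implant, background genes at 0.8 genes/kb (typical bacterial coding
density), a tRNA within 2 kb of an implant boundary with probability 0.5
plus far-away control tRNAs, and a hits table in which implant genes hit
their source phage at identity uniform on [85, 100] minus a 5% dropout
rate, while background genes draw a decoy hit at 1%. Everything is
deterministic given the seed, and the three artifacts (GenBank, truth BED,
hits TSV) are mutually consistent.

The generator deliberately omits codon structure, sequence-level homology
(hits are declared, not aligned), repeat content, and assembly artifacts.
Passing tests on these genomes therefore demonstrate the algorithmic
contracts — recovery of dense implanted hit clusters, correct evidence
arithmetic, correct bookkeeping — not performance on real genomes, which
depends on the phage database and annotation quality.

Problem sizes used by the package's own studies: the end-to-end study runs
20 genomes of 200 kb with 2–4 implants of 15–35 kb each (four implants of
up to 45 kb cannot be placed in 200 kb with sane margins); the G+C study
runs 100 genomes of 60 kb with a single 8–12 kb implant, where the +0.10
shift is ≈ 2.5 window-SDs and the implant occupies a realistic minority of
the sequence.

## Degenerate inputs and edge behaviour

* Fewer phage-homologous genes than MinPts: everything is noise, with a
  warning — not an error, since an empty result is a legitimate finding.
* A genome shorter than the G+C window: one window over the whole sequence,
  with a warning.
* CDS lengths not divisible by 3 (sloppy annotations): the longest in-frame
  prefix is translated, with a warning, rather than aborting.
* Compound (`join`) CDS locations collapse to their outermost span — the
  clustering and evidence stages only need the genomic extent.
* An empty hits table, or zero resulting regions, is a successful run.
* Multi-record flat files: each record should be processed independently;
  the readers handle one record per file.

## Known limitations

* Identity is measured over the aligned region with no coverage threshold;
  short high-identity alignments of long genes can pass the filter.
* The G+C baseline includes the prophages themselves (see above).
* No intact/questionable/incomplete grading, no functional annotation via
  web services, and no protein aligner is bundled — the tool remains fully
  usable offline from a precomputed hits table.
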