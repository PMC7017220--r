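---
title: "Mining terrestrial isopod transcriptomes for antimicrobial peptides"
author: "isoamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining terrestrial isopod transcriptomes for antimicrobial peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoamp)
```

## The problem

Terrestrial isopods (Oniscidea) defend themselves with three antimicrobial
peptide (AMP) families: anti-lipopolysaccharide factors (ALF), crustins, and
the lineage-specific, glycine-rich armadillidins. `isoamp` implements the
complete computational side of an AMP-mining study of this system: starting
from transcript contigs it finds candidate peptides by homology, validates
them against family hallmarks, classifies crustins into the two published
type schemes, and characterizes armadillidin mature peptides (motif content,
composition, average mass, theoretical pI, family consensus). A seeded
synthetic transcriptome generator plants known precursors so that every
stage can be tested against ground truth with no external data.

## Pipeline model and assumptions

The pipeline follows the classical homology-mining design:

1. **Redundancy collapse.** Contigs are clustered greedily at 95% nucleotide
   identity (the CD-HIT convention: records sorted by length, each joining
   the first cluster whose representative matches; identity = matches over
   the shorter sequence length, computed on a global alignment, `N` never a
   match). A shared-11-mer screen skips alignments between obviously
   unrelated contigs; it is a plain containment count, not CD-HIT's word
   statistics, and cannot reject a pair above the identity threshold because
   95%-identical sequences of the lengths considered always share far more
   than the five required 11-mers (low-complexity sequences with fewer
   distinct 11-mers fall back to alignment).
2. **ORF translation.** ORFs are maximal stop-free codon runs in all six
   frames (stop-to-stop; contig edges count as boundaries), not
   Met-anchored: on fragmentary contigs this maximizes recovered coding
   sequence. Each representative contributes its longest ORF (ties: frame
   order `+1,+2,+3,-1,-2,-3`, then smaller start). Codons containing `N`
   translate to `X`, and `X` never counts as an alignment match.
3. **Homology search.** Candidates are scored against one reference peptide
   per family by exhaustive Smith-Waterman with affine gaps (BLOSUM62,
   gap open 11, extend 1) — exact and heuristic-free at this scale — with
   Karlin-Altschul E-values (`E = K m n e^{-lambda S}`, gapped BLOSUM62
   constants lambda = 0.267, K = 0.041, `n` = database residue count) and
   the study's cutoff E <= 1e-10. Traceback ties are fixed (diagonal, then
   up, then left) so reported alignments are reproducible.
4. **Reciprocal confirmation.** A hit is kept only if the subject, searched
   back against the full reference set, finds a member of the same family
   as its best hit. This replaces an online database cross-check with a
   self-contained equivalent.
5. **Domain validation.** Transparent rules stand in for HMM domain scans
   and signal-peptide prediction (below). Candidates failing their family's
   rules are discarded, then the family length filters are applied (ALF
   >= 100 residues, crustin >= 90).
6. **Classification and characterization** (below).

## Signal peptides and family rules

Signal peptides are called by a hydropathy heuristic: candidate cleavage
sites between positions 10 and 40 require a hydrophobic core (best
8-residue window of Kyte-Doolittle values, mean >= 1.5) and small residues
(`A,G,S,C,T`) at positions -3 and -1 — the signal peptidase I preference.
Candidates are ranked by small-residue quality (A = 2, G/S = 1, C/T = 0.5,
summed over -3 and -1) minus the mean hydropathy of the five residues after
the site; the subtraction anchors the site at the exit of the hydrophobic
core and prevents it from drifting into a hydrophobic mature N-terminus
(ALF precursors would otherwise lose their first mature residues to the
"signal"). Remaining ties go to the longest signal, which selects the final
`A` of the classical `A-X-A` motif.

Family hallmarks are operationalized as explicit thresholds:

* **ALF**: mature region of 70-160 residues (an 8-14 kDa single-domain
  peptide), mean Kyte-Doolittle of the first 25 mature residues >= 0.5,
  and a cysteine pair separated by 15-55 residues (the LPS-binding loop).
  Any pair qualifies, so the rule is robust to incidental cysteines inside
  or outside the loop; cysteine-dense crustins are excluded not by this
  check (a WAP domain can contain a pair at loop spacing) but by the
  hydrophilic N-terminus of their mature peptides, and the packaged
  fixtures confirm the two annotations never co-fire.
* **Crustin**: a window of 35-60 residues holding >= 8 cysteines and
  overlapping the C-terminal half (the WAP domain). Canonical single WAP
  domains carry 8 cysteines; the "12 conserved cysteines" often quoted for
  the family is treated as a family-level alignment statement and reported
  by `flag_conserved_cys()` (>= 12 alignment columns that are >= 90%
  cysteine), not enforced per sequence. Disjoint qualifying windows are
  counted over the whole peptide for multi-WAP detection.
* **Armadillidin**: mature region >= 25% glycine with >= 2 glycine runs of
  length >= 3 — the GGGX architecture.

## Crustin typing

Under the G-rich-region scheme a crustin is type II when its glycine-rich
region is >= 100 residues, >= 20% glycine, and holds >= 3 repeated
tetrapeptides; otherwise type I. These thresholds sit inside the empty gap
between the published value ranges of the two groups (type II: regions of
130-166 residues at 24.6-32.3% G with 3-11 repeats; type I: <= 62 residues,
<= 9.8% G, no repeats), so any sequence matching either published range is
classified unambiguously. The G-rich region itself is the best 20-residue
window of glycine density >= 0.20, grown outward in adjacent (possibly
partial) windows that each hold the density; growing in window-sized blocks
rather than residue by residue keeps a long flanking stretch of
glycine-free sequence from being annexed on the strength of the core's
density. A tetrapeptide is "repetitive" when its total (overlapping)
occurrence count in the region is >= 2; the region is then scanned left to
right without overlap and every repetitive tetrapeptide scanned is counted.
Under the domain-organization scheme, >= 2 WAP windows give "multi-WAP", a
qualifying G-rich region before the WAP domain gives type II, else type I.

## Armadillidin characterization

Glycine runs are maximal stretches of >= 2 consecutive `G`; every run of
length >= 3 contributes one GGGX motif whose `X` is the residue after the
run. This convention reproduces the printed per-species run counts that are
internally consistent (7 runs in *C. elongata*, 6 in *P. dispar*, six GGGF
copies in *A. versicolor*); where the published per-species motif counts
are not reproducible under any single convention, both the run count and
the motif count are reported and neither is asserted. Over-representation
of a residue is strictly more than 10% of mature length, glycine excluded.

Average mass is the sum of IUPAC isotope-averaged residue masses plus one
water, free unmodified termini. The theoretical pI solves
`net charge(pH) = 0` by bisection on pH 0-14 to |charge| < 1e-4 under a
Henderson-Hasselbalch model with the Bjellqvist pKa set (terminal pKa
values depending on the terminal residues) — the same model behind the
ProtParam values that published peptide tables cite. Both tables are pinned
in the package so results are bit-stable; reported table values are rounded
half-up to one decimal. On the packaged fixture of 18 printed mature
sequences the table reproduces every printed length and glycine percentage
exactly, and every mass and pI within 0.05 units.

One published statistic is not reproducible from the printed sequences: the
claim that arginine exceeds 10% of mature length in 14 of the 17 organisms.
The strict rule applied to the printed sequences yields 16 — only
*A. officinalis* (7.0%) falls below, and the nearest others sit at
10.4-10.9%. The package reports the computed value; the corresponding
acceptance test records the discrepancy as a failing expectation rather
than weakening the rule.

## Multiple alignment and consensus

The progressive aligner builds a UPGMA guide tree from pairwise global
identity distances and merges profiles with "once a gap, always a gap".
Gap penalties in the profile merge are scaled by the non-gap fraction of
the opposing column (CLUSTAL-style position-specific penalties) and ties
into the match state prefer closing a gap over the diagonal; together these
keep the register of repeated units consistent, which matters for peptides
built from near-identical GGGX repeats where gap placement is otherwise
score-degenerate. Alignment trimming drops columns that are more than 50%
gaps, then retained runs shorter than 5 columns — a permissive, two-rule
block filter in the spirit of the "less stringent" settings of alignment
trimmers. The column consensus groups residues into physico-chemical
classes (`AVLIM`, `FWY`, `ST`, `DE`, `NQ`, `KRH`, `C`, `G`, `P`); a column
emits its modal residue when residue or class agreement reaches the 70%
threshold, with gaps counting against conservation. Emitting the modal
residue (not a class symbol) keeps consensus strings comparable to
published ones. On the eight Armadillidiidae mature sequences the consensus
contains the family anchor `RPYIGGGG` and at least three `GGGF` copies,
robustly under input permutation; exact spacer lengths depend on gap
placement and are not asserted.

## The synthetic generator

`generate_transcriptome()` emulates the study inputs: per species it plants
one precursor per family — a 19-residue A/F-rich signal peptide with an
`A-X-A` cleavage motif followed by a family mature template (armadillidin:
the printed *A. vulgare* H mature; ALF: a synthetic 103-residue peptide
with a hydrophobic N-terminus and a cysteine pair 25 apart; crustin: a
synthetic WAP domain with 12 cysteines behind either a short low-G region
or, in alternating species, a 130-residue G-rich repeat region) — among
ORF-poor random background transcripts. Divergence is modelled at the
amino-acid level (default 5% per residue) with the family-diagnostic
residues (ALF and WAP cysteines, the signal anchor positions) held
invariant: an explicit, if crude, model of the purifying selection that
makes those residues usable as diagnostics in real data, which also keeps
planted frames free of nonsense codons. The mutated precursor is
reverse-translated with uniform synonymous codons, framed by an in-frame
upstream stop and a stop codon, flanked by stop cassettes covering all six
frames and random UTRs (30-150 nt), and placed on a random strand; UTRs and
codons are resampled until the precursor is the unique longest ORF, so
longest-ORF translation provably recovers it. Everything is deterministic
given the seed.

What the generator does **not** model: codon bias, expression levels,
splice isoforms, assembly artifacts, sequencing error, and real inter-fold
sequence diversity within a family (each family descends from one
template). Passing recovery tests therefore demonstrates the pipeline's
mechanics — search sensitivity at the stated divergence, rule specificity
against random background, correct bookkeeping — not performance on real
transcriptomes, where repertoire counts depend on search parameters and
assembly quality in ways a desk-scale exercise cannot reproduce. For the
same reason, published repertoire sizes (110 ALFs, 73 crustins, per-species
means) and the published phylogenetic cluster topologies are out of scope.

## Numerical choices and degenerate inputs

Alignment scores are exact dynamic programming; E-values use the published
gapped BLOSUM62 constants rather than re-estimated ones. The pI bisection
always converges because the charge function is strictly decreasing. An
empty transcript set produces empty reports with a warning rather than an
error; a peptide of `X` has no defined mass and raises an error; a sequence
with no ORF yields an explicit zero-row result. Reports are written with
fixed column order and no locale-dependent formatting, so reruns on
identical input are byte-identical.

Problem sizes used by the test-suite and the reproduction script — 200
random alignment pairs of 20-40 residues against a brute-force dynamic
programming oracle, 1000 random G-rich strings against an enumeration
oracle, and the 21-species synthetic study (210 transcripts, 63 planted
AMPs) — were chosen as the smallest sizes at which each property is
exercised across all code paths.

## Known limitations

The signal-peptide heuristic is a hydropathy rule, not a trained model; its
cleavage sites on real precursors should be treated as estimates. Family
rules are thresholds, not profile HMMs, and will not separate remote
homologs the way Pfam models do. The progressive aligner does no iterative
refinement; for publication-grade alignments of divergent families a
dedicated aligner should be used, with this package's consensus applied to
its output via `new_msa()`.
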