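---
title: "Quantifying bacterial base-editing outcomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial base-editing outcomes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baseditr)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, and the choices made where the design was genuinely
open. The README shows the code; here we explain the science.

## The measurement problem

A base editor delivered to a bacterial population converts A·T to G·C (ABE)
or C·G to T·A (CBE) inside an editing window of its protospacer, without a
double-strand break. Assessing such an intervention asks four questions:

1. *Did the intended edit happen, and in what fraction of the population?*
2. *What else got edited in the window (bystanders)?*
3. *Did anything get edited elsewhere (guide-dependent off-targets, or a
   global deaminase-driven elevation of the mutation rate)?*
4. *What do orthogonal readouts — selective plating, droplet PCR — say about
   the same fraction?*

Each question maps to one module of the package, and a synthetic-data
generator ties them together by producing inputs with known truth.

## Coordinates and protospacer numbering

All coordinates in this package are **1-based inclusive**, the convention of
R, Bioconductor ranges and the textual SAM format alike; using one frame
end to end removes a conversion step that is a classic source of
off-by-one errors. Protospacer positions are numbered **1–20 from the
PAM-distal 5′ end**, the standard SpCas9 convention, so "position 7" is the
seventh spacer base and position 20 abuts the PAM. For a minus-strand site
spanning reference positions $[s, e]$, protospacer position $p$ sits at
reference coordinate $e - p + 1$ and all bases are complemented before any
counting. An ambiguous reference base `N` is treated conservatively: it
mismatches every concrete base, and matches only the wildcard `N` of a PAM
pattern.

## Guide design for gene inactivation

Two inactivation strategies are implemented.

**Premature stop codons (CBE).** A C→T conversion creates an in-frame stop
from the sense codons CAA (→TAA), CAG (→TAG) and CGA (→TGA); TGG becomes a
stop by editing the antisense CCA — one C gives TAG or TGA, both give TAA.
Rather than hard-coding these four cases, the designer enumerates every
non-empty subset of in-window, in-frame cytosines on each PAM-adjacent
protospacer, applies the subset, and keeps it when re-translation of the CDS
gains a premature stop; every emitted design is therefore verified by
construction, and the four codon cases emerge as the complete set of
productive patterns. All subsets are enumerated because with a multi-C codon
(CCA) the achievable product depends on which cytosines the deaminase hits,
and that is not under the designer's control; each achievable product is
reported as its own design.

**Start-codon disruption (ABE).** Two geometric classes exist: a
template-strand protospacer whose window covers the adenine pairing the T of
ATG (coding ATG→ACG), and a coding-strand protospacer whose window covers
the start adenine itself (ATG→GTG). Both are reported with their class,
since ACG and GTG starts differ in residual initiation activity and a user
may prefer one.

The **editing window defaults to positions 4–8** for both chemistries — the
canonical high-activity window of the deaminases in use. Deamination outside
it is well documented, so candidate *bystander* bases are additionally
reported over positions 1–12; observed bystander edits at positions 1 and
9–11 in deep-sequencing data motivate that wider reporting range. Ties
between equally valid designs are broken by the distance of the edit to the
window centre, then by genomic start — determinism, not biology.

## The off-target candidate rule

Candidate off-target sites are every protospacer occurrence (both strands,
NGG PAM) with at most **7 mismatches** to the spacer, of which at most **2
in the 10 PAM-proximal positions** — mismatches near the PAM are the ones
that most strongly abolish Cas9 binding, hence the tighter budget there. The
PAM is matched, never counted as a mismatch; the on-target (0-mismatch) site
is returned and flagged rather than suppressed, since reports conventionally
plot it alongside the off-targets. Both strands are scanned: protospacers
are strand-specific and a one-strand scan would miss half the search space.

The production scan vectorises the comparison (PAM-anchored windows,
matrix mismatch counting); a literal per-window, character-by-character
`brute_force_candidates()` ships in the package as the reference
implementation. The two are required to agree *exactly* — the test suite
checks set identity on 100 random 5-kb genomes with planted decoys at
(mismatch, proximal) = (0,0), (3,0), (7,2), (7,3) and (8,0), of which the
last two must be excluded by the rule. Five kilobases per genome keeps the
intentionally unoptimised oracle fast while exercising every branch of the
rule; the optimised scan itself handles megabase genomes.

## Pileup and the read-mismatch frequency

`build_pileup()` converts alignments into per-position A/C/G/T counts and
the read-mismatch frequency — mismatching aligned reads over total aligned
coverage. Counting follows the literal definition: aligned
(match/mismatch) bases only, no contribution from insertions or deleted
positions, and unmapped/secondary/supplementary records skipped. By default
**no base-quality or mapping-quality filter is applied and duplicates are
kept**: the statistic is reproduced exactly as defined, and `--min-baseq` /
`--min-mapq` are exposed for users who want filtering. Columns with zero
coverage, or whose reference base is N, carry an `NA` frequency and are
excluded from downstream comparisons rather than silently treated as zero.
The htslib pileup engine (via Rsamtools) does the format-level work;
the statistic and its contracts are the package's own.

## Editing-window profiling and bystander calls

For each protospacer position whose strand-oriented reference base equals
the editor's substrate (A or C), the edit fraction is the fraction of
covering reads carrying the product base (G or T). Positions that are not
editable carry `NA`, not 0 — "no substrate" and "substrate, unedited" are
different facts. Bystanders are editable non-target positions with a
fraction of at least **0.05** (default): at several-thousand-fold coverage
this cleanly separates genuine bystander deamination (tens of percent in
practice) from sequencing error (a few tenths of a percent). The on-target
efficiency is reported as the target-position fraction; a per-molecule
"any-edit" statistic would require read-level haplotypes, which column-wise
pileups deliberately do not retain.

## Treated-versus-control comparisons

Per candidate site, the report shows the **mismatch frequency of the base
with the highest frequency** across the 20 protospacer positions, in the
treated and the control sample, and flags a site when treated exceeds
control by more than an absolute **0.005** — about three times the 0.1–0.3%
per-base error scale of Illumina sequencing, below which a difference is
not interpretable. Base ties are broken alphabetically for determinism.
Sites covered below `min_cov` (default 100) in either sample are reported
with an insufficient-coverage status, never dropped.

Genome-wide, a deaminase-driven elevation of the mutation rate would make
*more* positions exceed the control than the reverse. The scan counts
exceedances in both directions over commonly covered positions (optionally
restricted to adenine or cytosine reference positions) and applies a
two-sided **binomial sign test at level 0.05** on the direction of
exceedances; "no elevation" is returned when the two counts are
statistically indistinguishable. The sign test was chosen because it makes
no distributional assumption about per-position error rates, which vary
with sequence context; it answers exactly the qualitative question asked
("are elevated positions more common in the treated sample?").

## Droplet PCR quantification

The assay partitions template molecules into ~20,000 droplets and reads two
competing probes on the same amplicon: FAM reports the unedited allele, HEX
the edited one. Because the two genotypes reside on distinct template
molecules, the channels are **independent Poisson loadings**, and each
channel's mean occupancy is recovered from its own negative-droplet
fraction, $\lambda = -\ln(n_{neg}/n_{total})$; double-positive droplets
need no special treatment under this model. The edited fraction is
$\lambda_{HEX}/(\lambda_{FAM}+\lambda_{HEX})$. The 95% interval comes from
the delta method: $\mathrm{Var}(\hat\lambda) = (1-p_{neg})/(n\,p_{neg})$
per channel, propagated to the ratio. Probe cross-reactivity is assumed
zero — the locked-nucleic-acid probe design puts ~11 °C of melting
temperature between matched and mismatched binding — and a saturated
channel (no negatives) is an error, not a number.

## Plate counts and the delivery model

Editing a resistance gene removes growth on selective plates, so a fold
reduction $F$ in selective colony counts (control over treated, plated
identically) implies an edited fraction $1 - 1/F$: $10^4$-fold means
99.99%. The simulator draws the treated selective count as
Binomial($n$, $1-f$) and censors the fold at $n$ when the count is zero.

Delivery versus multiplicity of infection follows the **single-hit Poisson
model** $f(\mathrm{MOI}) = 1 - e^{-a\,\mathrm{MOI}}$: each particle
independently delivers with effective probability $a$, and $f(0)=0$ is
enforced by the form. One observation gives the closed form
$a = -\ln(1-f)/\mathrm{MOI}$; several are fit by least squares with $a$
bounded in $(0, 1]$.

## What the synthetic generator does and does not emulate

`make_genome()` / `simulate_reads()` produce an i.i.d. random genome with a
planted protospacer (and optional decoys with exact mismatch structure),
then uniform single-end reads in which each molecule overlapping the site
carries the target edit with probability $f$ and each bystander edit per
the linkage model, plus uniform substitution errors. Defaults mirror the
deep-sequencing conditions the estimators are meant for: **coverage 6,000,
read length 100, error rate 0.3%**; recovery simulations use a 1-kb genome,
which at that coverage gives ~60,000 reads and keeps a full loop in
seconds. Bystander fractions in the bundled recovery experiments are set to
0.3, a representative mid-range bystander level.

Positions are edited **independently** by default: column-wise pileup
frequencies carry no information about co-occurrence on molecules, so
linkage is unidentifiable from the data the analysis consumes; a
conditional-on-target mode exists for sensitivity checks. Reads are
error-uniform, fixed-length, single-end, indel-free (M-only truth
alignments emitted directly, since substitutions are what the analysis
measures). Real Illumina data adds quality-dependent and context-dependent
errors, PCR duplicates, indels and mapping ambiguity — so passing recovery
tests here validates the *estimators*, not the upstream alignment pipeline.

A subtlety the tests respect: with per-base error $e$, the expected
product-base fraction at a position with true edit fraction $f$ is not $f$
but $f(1-e) + (1-f)e/3$ — errors erode edited reads and occasionally mimic
edits. At $f = 0.98$, $e = 0.003$ the bias (≈ −0.003) is comparable to the
binomial standard error at coverage 6,000, so recovery tests compare the
observed product-base count against the 99% binomial interval at that
corrected probability: the exact sampling distribution of the estimator
under the simulation model.

## Numerical and degenerate-input choices

* Zero-coverage and reference-N pileup columns: `NA`, excluded downstream.
* Saturated ddPCR channels: error (occupancy unbounded), with a "both
  saturated" variant distinguished in the message.
* Fold reduction below 1 rejected; fold 1 maps to edited fraction 0.
* All-zero delivery fractions: explicit fit failure.
* Empty candidate or design sets return typed zero-row tibbles, so
  downstream joins and writers behave.
* All randomness is seed-threaded (`sim_config(seed = )`, per-function
  `seed` arguments); identical configurations are byte-identical, which the
  suite verifies on FASTQ/SAM output.

## Known limitations

* No per-read haplotyping of co-occurring edits; frequencies are columnar.
* No bulge/indel off-target candidates and no activity scoring (CFD-like
  models) — the candidate rule is purely positional.
* The pileup consumes alignments; it does not align. Truth SAMs from the
  simulator bypass mapper behaviour entirely.
* The ddPCR model ignores probe cross-talk and droplet-volume variation;
  an optional cross-talk parameter exists in the simulator only.
* Guide designs are not ranked by predicted editing activity; no public
  activity model covers these bacterial contexts.
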