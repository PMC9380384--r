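---
title: "Designing allele-specific CRISPR-Cas9 guides against somatic mutations: models and methods"
author: "somaguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing allele-specific CRISPR-Cas9 guides against somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaguide)
```

## The problem

Tumor genomes typically carry on the order of one somatic mutation per
megabase — several thousand events genome-wide — that the patient's
normal cells do not share. A CRISPR–Cas9 nuclease programmed against the
*mutant* sequence can therefore create double-strand breaks only in
tumor cells, provided two conditions hold:

1. **Allele discrimination.** The guide must cut the tumor allele but
   not the normal allele at the same locus.
2. **Genome specificity.** The guide must not have a cleavable target
   anywhere else in the normal genome.

`somaguide` turns a reference genome plus a tumor-unique somatic VCF
into a ranked, constraint-respecting panel of such guides, and provides
the two estimators that make the strategy quantitative: how many
suitable sites a tumor of a given mutation burden offers, and how likely
a panel is to survive ongoing clonal evolution.

## Coordinates and variant model

Internally every interval is 0-based half-open (BED-native); VCF
positions are converted on input (`pos − 1`) and back on output. Variants
are normalized before design: shared leading/trailing allele bases are
trimmed to parsimony (one anchor base kept, VCF-style) and indels are
shifted to their leftmost equivalent placement. Normalization is
idempotent, so every equivalent encoding of the same indel collapses to
one canonical id `contig:pos:ref>alt` — which is what makes the
tumor-vs-normal set difference and all clone-overlap arithmetic exact
set operations on ids.

Around each variant a **haplotype window** is built: the reference
sequence `W` bases either side (default `W = 30`; any value ≥ 23
guarantees that every 23-nt protospacer+PAM frame touching the altered
bases lies wholly inside the window, and 30 adds slack for indels) and
the tumor haplotype obtained by applying REF→ALT. An offset map links
every tumor-window base back to its genomic coordinate; bases inserted
by the tumor allele map to nothing and are flagged as such.

The *altered span* of the window marks what is tumor-specific:

* SNV/MNV — the substituted bases (for an MNV only the bases that truly
  differ; a parsimony-trimmed MNV can still contain matching interior
  bases, which are not counted as discriminating).
* Insertion — the inserted bases.
* Deletion — the two bases flanking the novel junction. A guide counts
  as overlapping a deletion only if it spans the junction (contains both
  flanking bases): a frame ending on the anchor base, or starting just
  after the junction, reads pure reference sequence and carries no
  tumor-specific signal.

Windows hold one variant each. Plain VCFs carry no phase, so
co-occurring nearby variants are never co-applied; variants with a
neighbour inside their window are flagged (`flag_crowded_variants`) and
the synthetic spike-in generator spaces variants ≥ 50 bp apart so the
supported path is what fixtures exercise.

## Guide nomination

SpCas9 geometry is fixed once: a 20-nt protospacer with a 3-nt `NGG`
PAM 3' of it. `scan_pam_sites` enumerates every frame on both strands of
the tumor window (forward: `GG` at frame positions 21–22; reverse: `CC`
at positions 0–1 of the reverse-complement layout); frames containing
`N` are dropped rather than erroring. Protospacer positions are numbered
**PAM-proximally** (position 1 adjacent to the PAM), the convention in
which seed rules are stated in the CRISPR literature; PAM positions are
reported as P1–P3. Only `NGG` nominates — `NAG` is honoured solely as a
permissive PAM in the off-target search.

The reported cut site is the single base immediately PAM-distal of the
blunt cut between protospacer positions 3 and 4. This convention is
exactly mirror-symmetric under reverse complement, which the
strand-symmetry tests exploit. Guides falling entirely inside inserted
tumor sequence have no reference cut coordinate; they are kept (pure
tumor-only sequence is maximally specific) and marked
`within_insertion`.

## Allele-specificity classes

Each candidate receives exactly one class, in precedence order:

| class | rule | default weight |
|---|---|---|
| `PAM_GAIN` | the normal allele lacks `NGG` at the candidate's PAM frame/strand | 3 |
| `INDEL_DISRUPTING` | variant is an INS/DEL whose altered span or junction intersects the frame | 2 |
| `SEED_DISCRIMINATING` | SNV/MNV with ≥ 1 altered base at protospacer positions 1..`seed_len` | 1 |
| `NON_DISCRIMINATING` | none of the above | 0 |

Two deliberate choices:

* The PAM check considers only P2–P3 — the `N` position never
  discriminates.
* `PAM_GAIN` is evaluated only for length-preserving variants. Its
  definition requires the gap-free alignment of the guide frame onto the
  normal locus, which does not exist for an indel
  (`native_locus_mismatches` reports a frame-shift and an unbounded
  mismatch sentinel instead), so indel candidates classify as
  `INDEL_DISRUPTING` even when the inserted sequence happens to contain
  the PAM. The precedence order is preserved vacuously.

`seed_len` defaults to 12 with 8–12 the supported range: the
PAM-proximal 10–12 nt are the accepted Cas9 specificity determinant, and
a single seed mismatch usually — not always — abolishes cutting. Because
single-mismatch discrimination is the weakest mechanism, a **strict
mode** restricts the discriminating set to `PAM_GAIN` and
`INDEL_DISRUPTING`. Lowering `seed_len` can only shrink the seed class
(monotonicity is property-tested). Quantitative mismatch-efficiency
models (CFD-style scores) are out of scope; the classes are mechanistic,
not calibrated.

## Genome specificity

The normal genome is searched for gap-free (Hamming) matches of each
protospacer next to a permissive PAM (`NGG`, plus `NAG` by default,
reflecting SpCas9's known NAG tolerance). Bulge off-targets are out of
scope, as in most first-pass guide filters.

The production search uses a k-mer **pigeonhole index** (default
`k = 5`): a hit with ≤ m mismatches must contain at least one exact
k-chunk when the 20-mer is split into m + 1 disjoint chunks, so exact
k-mer lookups enumerate a candidate superset that is verified base by
base in compiled code; budgets beyond the pigeonhole regime fall back to
a full scan. An independent, vectorized pure-R exhaustive scan
(`find_matches_bruteforce`) serves as the correctness oracle, and the
test suite asserts exact hit-set equality between the two on hundreds of
random guides.

Filtering policy (all knobs in `offtarget_policy`):

* `reject_mm_threshold = 0` — only a *perfect* match elsewhere in the
  normal genome rejects a guide outright. Near-matches up to
  `report_mm = 3` are returned and penalize ranking instead. This keeps
  recall high; empirical off-target assays are the wet-lab counterpart
  of this predicted set and are not modelled here.
* `native_exclusion_radius = 50` bp — the normal allele at the variant's
  own locus (which a seed-SNV guide matches with exactly one mismatch)
  is the allele-discrimination question, not an off-target; it is
  reported separately and never counted.

## Scoring and panel selection

Hard filters first: GC in [0.30, 0.80], longest homopolymer ≤ 4, no
`TTTT` in the protospacer (a Pol III terminator for U6-driven sgRNA
expression). Survivors get

`composite = class_weight − Σ_hits 1 / (1 + mismatches)`.

The weights are ordinal heuristics — they encode the mechanistic
preference `PAM_GAIN > INDEL_DISRUPTING > SEED`, not measured
efficiencies. Selection is greedy by composite under a constraint
matroid: at most one guide per variant (panels target distinct mutation
sites), at most `max_per_contig = 2` guides per chromosome (the goal is
distributed damage, not fragmenting one chromosome), `N = 8` guides by
default — panels of 3–10 are all reachable via `panel_size`. Ties break
on a total order (score, fewer off-targets, contig, position, strand),
so a panel is a pure function of its input; tests assert byte-identical
re-runs and insensitivity to removing non-selected candidates. On small
instances greedy selection is compared against an exhaustive best-subset
oracle.

## Target-burden estimation

`estimate_suitable_fraction` estimates
`f = P(a random somatic variant admits ≥ 1 passing guide)` by Monte
Carlo: variants are drawn uniformly over a background genome (SNVs to a
uniform non-reference base; indels with probability `indel_fraction`,
insertion/deletion equiprobable, lengths geometric(0.5) capped at 10 —
small indels dominate somatic call sets), pushed through
nomination → classification → genome-specificity filtering, and the
suitable fraction is returned with an exact binomial 95% CI. Guide
*composition* filters (GC, poly-T) are intentionally not applied here:
the question is targetability of the mutation, not library design.
`expected_targets` then scales by the burden model:

`count = burden_per_mb × genome_mb × f`,

linear in both factors. Defaults: `burden_per_mb = 1.0` (the prostate
cancer cohort figure), `genome_mb = 3000` (human callable genome,
order-of-magnitude — the analysis denominator is configurable because
published burden figures rarely state theirs), and
`indel_fraction = 817723/4803421 ≈ 0.17`, the indel share of a
hepatoma whole-genome call set.

Problem sizes used by the packaged analyses: a 1-Mb i.i.d. background
genome at GC 0.41 with 10,000 sampled variants for the per-patient
estimate, and 50,000 variants for the call-set scale-up. At these sizes
the binomial CI is ±1% or tighter and a run takes a few minutes.

## Clonal persistence

`clone_overlap` reports exact id-set arithmetic between a parent tumor
and derived clones: `|A∩B|`, the one-sided differences,
`retained_fraction = |child∩parent|/|parent|` and
`unique_fraction = |child∖parent|/|child|`. No attempt is made to force
agreement between externally printed percentages and counts — published
clone comparisons often use denominators that are not recoverable — the
package reports the arithmetic of the sets it is given.

Panel survival under evolution uses an explicit independence model:
each targeted site is retained with probability `p_retain`, so
`P(all N lost) = (1 − p_retain)^N`. With `p_retain ≈ 0.81` (typical
endpoint retention of a passaged single-cell clone) and `N = 10`,
`P ≈ 6×10⁻⁸`. The simulator relaxes nothing about this model by default
(`derive_clone` retains ids i.i.d. and gains Poisson new mutations), so
`panel_survival_empirical` converges to the closed form — a
parameter-recovery test, not a tautology, since the empirical path goes
through the full clone-derivation machinery. Aggregate `p_retain` is
applied once rather than per passage because published clone data are
endpoint comparisons; the gain-rate default (53.5 mutations/passage,
i.e. ~3,200 over 60 passages) matches the same observations.

## What the simulator does and does not emulate

`simulate_genome` draws i.i.d. bases at a target GC (0.41 by default).
Real genomes are not i.i.d.: repeats, segmental duplications and
homopolymer-rich regions inflate off-target counts and would lower the
suitable fraction; mutational signatures concentrate variants in
specific trinucleotide contexts, which shifts the PAM-gain rate.
Passing tests on synthetic data therefore validate the *machinery* —
coordinate conventions, search exactness, classification totality,
estimator calibration — not the numerical transfer of `f` to any
particular tumor. For real use, supply the real reference FASTA and the
tumor's own VCF.

## Numerical and degenerate-input choices

* Ambiguity codes other than `ACGTN` become `N` on FASTA read; any `N`
  inside a frame disqualifies that candidate (or index/search position)
  silently rather than erroring.
* Symbolic/structural ALTs (`<DEL>`, breakends, `*`) are skipped on VCF
  read with a reconciled logged count — the strategy targets point
  mutations and small indels.
* Windows clipped at contig edges carry a flag; a variant on an unknown
  contig is an error.
* Empty inputs are valid everywhere they can be: an empty VCF designs an
  empty (warned) panel; an empty panel has survival 0 by convention.
* All stochastic entry points require an explicit integer seed and are
  bit-reproducible given it; nothing defaults to wall-clock randomness.

## Known limitations

Gap-free matching only (no DNA/RNA bulges); no chromatin or efficiency
modelling; no phased multi-variant haplotypes; no copy-number events or
trinucleotide mutational signatures in the simulator; clone retention is
modelled as exchangeable and independent across sites, which real
subclonal structure violates in the direction of positive correlation —
the closed form is then optimistic for panels targeting mutations on the
same subclone, which is why panels spread across variants and contigs.
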