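---
title: "Methods: UMI-consensus amplicon profiling of mutagenic repair at nicks and DSBs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UMI-consensus amplicon profiling of mutagenic repair at nicks and DSBs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nickmut)
```

## The measurement problem

CRISPR ribonucleoproteins can place either a single-strand nick (Cas9 D10A)
or a double-strand break (wild-type Cas9) at a chosen genomic position.
Repair of these lesions occasionally leaves a scar — a deletion, an
insertion, a single-nucleotide variant (SNV), or a donor-templated edit —
and the frequency and spatial structure of those scars carry mechanistic
information: nicks are roughly an order of magnitude less mutagenic than
DSBs, their deletion and SNV footprints are distributed *asymmetrically*
around the nick (consistent with resection that runs predominately in one
direction), and their insertions are almost always a single base whose
identity depends on the local sequence.

Measuring per-molecule mutation frequencies in the 0.1–5% range by amplicon
sequencing is dominated by two error sources: polymerase errors introduced
during library PCR and base-calling errors on the sequencer. `nickmut`
implements the standard countermeasure — unique molecular identifiers
(UMIs) attached before amplification, followed by single-strand consensus
sequence (SSCS) assembly per UMI family — together with a bespoke,
amplicon-scale variant caller, so that a single code path runs from raw
FASTQ to background-subtracted per-position mutation maps.

## Pipeline model

The pipeline has four stages, each exposed as an R function and chained by
`run_all()`:

1. **UMI extraction and family grouping** (`extract_umi_pairs()`,
   `group_families()`). Each mate begins with a `umi_len` (default 10 nt)
   random tag followed by a locus primer; the primer is verified with at
   most `max_primer_mismatch` (default 2) mismatches and trimmed. Families
   are keyed by the *ordered* tag pair (a, b) from read 1 and read 2 — the
   "ab" form. We deliberately do no UMI error correction: merging
   near-identical tags would silently change family counts, and collisions
   over 4^20 ordered pairs are vanishingly rare at library scale
   (birthday-problem expectation below 1e-3 for 10^4 molecules).

2. **SSCS assembly** (`sscs_consensus()`). Families smaller than
   `min_family_size` (default 3) are dropped and counted. Per position the
   modal base is emitted when its fraction among contributing members
   reaches `consensus_threshold` (default 0.7), else `N`. These defaults
   mean a lone sequencing error in a family of three masks a position to
   `N` (a wildcard downstream) rather than flipping it; consensus is
   count-based and ignores quality strings, which carry no information in
   the simulator and little at the consensus stage in practice. Length
   disagreements resolve to the modal member length.

3. **Alignment and event extraction** (`semiglobal_align()`,
   `extract_events()`, `left_align_indels()`). Consensus mates are aligned
   to the amplicon by an affine-gap semi-global dynamic program: the query
   aligns end-to-end while reference end gaps are free, so a molecule
   carrying a large internal deletion aligns as one deletion operation
   instead of being soft-clipped. The default scheme is match +2,
   mismatch 4, gap open 6, gap extend 1 (a gap of length k costs
   `open + k * extend`), BWA-like magnitudes. Tie-breaking is
   deterministic — diagonal over gap, deletion over insertion, leftmost end
   column — so event coordinates are reproducible. `N` is a zero-reward
   wildcard. A gap-free wildcard-exact placement attains the per-base score
   bound, so such placements short-circuit the dynamic program; this is an
   optimization, not an approximation. Indels are then shifted to their
   5'-most equivalent position and annotated with the full interval of
   equivalent start positions, mirroring the genuine ambiguity of insertion
   placement in repeated context (a +1G at a T|G cut forms TGG whether
   inserted at the nick or 1 bp 3' of it; we left-align and record the
   span rather than guess).

4. **Calling and profiling** (`call_molecules()`, `condition_summary()`,
   map and histogram functions). Events are restricted to a scoring window
   (default 65 bp centered on the cut bond, the 3' side holding the extra
   position for odd widths). Indels are accepted from either mate and
   deduplicated on their normalized signature; molecules whose mates report
   *conflicting* indels over the same span are flagged discordant and
   removed from all denominators. SNVs obey a dual-strand confirmation
   rule: under the default `mate_overlap` mode an SNV is kept only when
   both mates cover the position and report the same alternative base. The
   amplicon geometry guarantees the scoring window lies inside the mate
   overlap, so this check is available for every molecule; a `duplex` mode
   (confirmation against the reciprocal (b, a) family) and an unconfirmed
   `single` mode exist for comparison. SNVs inside an accepted deletion
   footprint are suppressed as unalignable. Donor-templated (a-HDR)
   molecules are those carrying exactly the configured donor replacement
   and nothing else over its footprint; their donor events are excluded
   from the SNV/indel categories.

Frequencies are reported per *molecule* (a molecule with one or more
deletions counts once toward the deletion frequency; event-level counting
is available via `counting = "event"`), with the denominator being
consensus molecules whose mates both cover the window. Background
subtraction — per-category fractions measured from an uncut control, or
supplied numbers such as `default_background_panel()` (insertions 0.47%,
deletions 0.3%, SNVs 0.26%) — is applied to aggregate frequencies only and
floored at zero; per-position maps are reported raw, with the control map
alongside, because positionwise subtraction has no agreed convention.

Sequencing depth is summarized as fold coverage `N * L / G` from the
aligned consensus read count, mean read length and amplicon size;
`round_coverage()` reproduces the conventional nearest-500 display
rounding.

### Asymmetry index

Resection signatures are quantified by
`A = (M3 - M5) / (M3 + M5)`, where `M5`/`M3` sum per-position deletion (or
SNV) mass strictly 5'/3' of the cut bond. `A` lives in [-1, 1], is 0 for a
mirrored profile, and is reported with a percentile bootstrap interval over
molecules (`asymmetry_bootstrap()`). Note that indel left-normalization
systematically moves ambiguous deletions 5', so `A` is a conservative
estimate of 3'-heavy asymmetry; in repeat-dense contexts this shrinkage can
be substantial.

## The synthetic-data generator

`simulation_config()` defines the study conditions; its defaults describe a
nick-targeted library in unperturbed cells:

| parameter | default | meaning |
|---|---|---|
| `p_mut` | 0.022 | fraction of molecules carrying a repair event (nick, control cells; DSBs run near 0.42, BRCA2-depleted nicks near 7-fold the control) |
| `class_mix` | 0.7 / 0.1 / 0.2 / 0 | deletion / insertion / SNV / donor-HDR |
| `del_extent_5`, `del_extent_3` | 10, 25 | deletion reach 5'/3' of the cut, the asymmetric resection zone |
| `del_q5`, `del_q3` | 0.85 | truncated-geometric extent parameters (P(L=k) ~ q^k); 0.85 lets deletions actually occupy the zone rather than hug the cut |
| `p_del_1bp` | 0.15 | point mass of exact 1 bp deletions at the cut |
| `ins_base`, `ins_len_probs` | G, {1: 1} | predominately +1G insertions at the cut |
| `snv_zone_5`, `snv_zone_3` | 10, 25 | SNV placement zone (same asymmetry as deletions) |
| `transversion_fraction` | 0.25 | baseline transversion share among SNVs (rises toward 0.7 under BRCA2 depletion) |
| `umi_len` | 10 | UMI length per mate |
| `family_lambda` | 4 | family size = 1 + Poisson(4), mean 5, minimum 1 |
| `e_pcr` | 1e-5 | per-base early-cycle PCR substitution, shared by the whole family |
| `e_seq` | 1e-3 | per-base per-read sequencing substitution |
| `read_len` | 268 | total read length including UMI and primer |

The default amplicon (`default_amplicon()`) is a synthetic 323 bp sequence
— the genomic-insert scale of a paired-end MiSeq amplicon design — with two
CRISPR target sites embedded 35 bp apart on opposite strands (cuts at 160
and 125), supporting dual-site co-nicking simulations. With 268 nt reads
the two ~236 nt payloads overlap across the middle of the insert, which is
what makes the mate-overlap SNV confirmation available at the scoring
window; this geometry is validated at configuration time. The sequence was
designed once with three properties: the deletion zone [cut-10, cut+25)
contains no base equal to the base at cut-11, so left-normalization cannot
push a zone deletion outside the zone; the zone is non-repetitive enough
that left-normalization preserves the 3'-heavy footprint; and the cut
context is T|G so +1G insertions reproduce the canonical TGG placement
ambiguity.

PCR error is modeled as a single early-cycle lineage substitution applied
once per molecule and inherited by every read of its family — exactly the
error mode SSCS cannot remove, and the reason UMI consensus is paired with
background subtraction rather than replacing it. Sequencing errors are
drawn independently per read. The generator does **not** model PCR
chimeras or jackpot amplification, quality-dependent error, indel
sequencing errors, or UMI re-tagging; family sizes are a stand-in
(1 + Poisson) since real family-size distributions are library-specific.
Consequences for interpretation: passing tests demonstrate correct
bookkeeping, error suppression, confirmation logic and parameter recovery
under this error model — they do not certify performance on real libraries
with chimeric reads, heteroduplexes or heavy jackpotting.

Two presets encode named conditions: `uncut_control_config()` raises
`e_pcr` to 4e-5 so the called SNV floor over the 65 bp window approximates
the ~0.26% uncut-control background of a representative amplicon panel
(0.26% / 65 = 4e-5); the default library keeps `e_pcr` at 1e-5 so that the
caller's per-class precision is limited by the science, not the floor. The
two needs — a realistic error floor and a clean recovery benchmark — pull
in opposite directions, so they are separated into two configurations
rather than compromised in one.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open on the top strand; a cut coordinate
  names the bond between `cut-1` and `cut`. The Cas9 cut is fixed 3 nt 5'
  of the PAM (blunt model); 1 nt overhang products are a repair-product
  interpretation, represented (if desired) in the simulator, not in the
  coordinate model.
* Even-width windows are balanced; odd widths give the 3' side the extra
  base. Windows are clipped to the amplicon with a warning.
* Probability vectors must sum to 1 within 1e-9; consensus threshold
  comparisons use a 1e-12 tolerance so `2/3 >= 0.667`-style boundary cases
  behave predictably.
* Deletion extents are drawn by inverse CDF over the finite support
  (exact, no rejection); the pair (L5, L3) is rejection-conditioned on
  L5 + L3 >= 1.
* Empty call sets raise errors rather than returning NaN frequencies;
  normalization to a reference at or below background is an error, not Inf.
* Ties in the consensus vote (two bases at equal count) emit `N`.
* One RNG stream per pipeline stage is derived from the master seed by
  hashing the stage name, so changing one stage's parameters does not
  perturb another stage's draws; all outputs are byte-reproducible under a
  fixed seed.

## Problem sizes

The validation suite and the reproduction script use libraries of 10^4
molecules (about 5 x 10^4 read pairs at the default family size), 200+
randomized alignment instances against an independent dynamic-programming
oracle, 1,000-molecule event round-trips, and 200-replicate bootstrap
intervals. These sizes give exact-binomial 99% recovery checks enough
resolution at the 2.2% nick mutation frequency while keeping a full run in
the minutes range on a single core.

## Known limitations

* The caller targets simple events within one amplicon: no structural
  variants, no multi-amplicon panels, no genome-scale mapping or off-target
  search.
* Duplex (ab/ba) confirmation is implemented but off by default; whether
  dual-strand confirmation should operate at the mate level or the
  duplex-family level is a genuine protocol ambiguity, and both modes are
  provided without asserting either as canonical.
* Left-normalization biases footprint maps 5' in repeated contexts (see
  above); the ambiguity span is recorded on every indel for consumers who
  want a different placement convention.
* Background subtraction assumes the control and condition libraries share
  an error process; the simulator can emulate a mismatch between the two,
  but the pipeline does not model it.
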