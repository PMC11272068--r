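---
title: "Composition-code fingerprinting: model, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-code fingerprinting: model, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compcode)
```

## The model

A protein's *composition code* is the vector of counts of selected residue
types — the residues for which selective labeling chemistry exists: Cys,
Lys, Met, Asp/Glu (one combined channel, since Asp and Glu share carboxylate
chemistry), Tyr, Arg, His, Trp and Ser. In an amplifiable fingerprinting
assay each channel is labeled with a DNA barcode in its own aliquot and
quantified by qPCR, so the measurement delivers *relative ratios* between
channels rather than absolute counts. Identification is database search: the
measured code is compared with the code of every entry in a
proteome-derived library by cosine similarity

$$\mathrm{sim}(u, v) = \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert},$$

and the entries are ranked. Cosine is the natural metric here because it is
invariant to overall scale — precisely the degree of freedom the assay
cannot observe — so libraries can store raw integer counts while queries
arrive as ratios normalized to the Lys channel. A query is *identified at
depth N* when its true entry ranks within the top N; *coverage* is the
fraction of library entries that would be identified by their own exact (or
noise-perturbed) code.

The model's assumptions, inherited from the assay it abstracts:

* labeling and quantification are linear in residue count (no
  sequence-context effects, no partial labeling);
* channels are measured independently, with independent errors;
* the analyte is a single purified or isolated species, present in the
  database.

## Channels, panels and termini

Panels are ordered lists of channels; the canonical incremental order is C,
K, M, D/E, Y, R, H, W, S, and `canonical_panel(k)` takes the first `k`.
Two termini conventions are provided because the chemistry acts on termini
as well as side chains, but whether a terminus is *free* depends on the
assay design:

* `"library-default"` counts residues only. This is the convention for
  proteome-wide sweeps, where nothing is known about terminal blocking.
* `"assay-matched"` adds the C-terminal carboxylate to the D/E channel
  (the carboxylate chemistry cannot distinguish it from a side chain), and
  optionally (`lys_n_terminus = TRUE`) the free N-terminal amine to the K
  channel. The option exists because the N-terminus is often occupied by a
  calibration dye — in that configuration it must *not* be counted —
  whereas an analyte captured by its C-terminus has a free N-terminal
  amine that the Lys chemistry will label.

The worked examples in the tests show both configurations in action: a
hormone peptide with an N-terminal dye uses the plain assay-matched panel,
while the amyloid-β peptide, C-terminally captured, counts its N-terminus
on the K channel (its theoretical K-channel value is 2 Lys + 1 N-terminus,
which is the only reading consistent with its published 0 : 1 : 0.33 : 0.33
ratio code).

Ambiguity codes B/Z/X and selenocysteine U count toward no channel: the
chemistry targets definite side chains, and a code should not change with a
database's ambiguity annotations.

## Search, ties and the uniqueness identity

Ranking is exhaustive — at proteome scale (tens of thousands of entries,
nine channels) a dense matrix product computes all similarities in well
under a second, so no approximate indexing is warranted. Processed chains
sharing a precursor are collapsed to one database entry represented by its
maximum-similarity member, so matching any mature product identifies the
precursor.

Ties must be handled explicitly because integer count vectors collide: two
entries with proportional codes have similarity exactly 1 with each other's
queries. Two policies are implemented:

* **conservative** (default): groups tied with the true group count against
  it — the query is identified at depth N only if strictly better groups
  plus tied other groups number fewer than N;
* **optimistic**: only strictly better groups count.

The conservative default makes noise-free top-1 coverage *equal* the
fraction of entries with unique code directions (`uniqueness_fraction()`),
which is the package's key internal consistency check and ties the coverage
machinery to a quantity that can be computed independently by hashing
normalized codes.

Numerically, "tied" means within `tie_tol = 1e-9` of the true group's
similarity, and uniqueness hashes unit-normalized codes rounded at 1e-9.
The shared resolution keeps the identity exact despite floating-point
cosines of parallel integer vectors (e.g. `(1,2,3)` vs `(2,4,6)`) not being
exactly 1. Rank order among non-tied entries uses full double precision;
ranked reports additionally break exact ties by ascending record id so
output is reproducible across platforms and BLAS implementations.

Degenerate codes are defined deterministically rather than left to NaN:
two all-zero codes have similarity 1 (they are identical), and exactly one
all-zero code has similarity 0.

## Secretome extraction

Secreted proteins circulate as processed products, so secretome libraries
are built from feature-annotated mature chains rather than precursor
sequences. The extractor takes UniProt-style entries (flat text or a TSV
export), keeps entries annotated "Secreted" in their keywords or
subcellular location, and slices one record per feature of kind `CHAIN`,
`PEPTIDE` or `PROPEP` (1-based inclusive coordinates, converted and
unit-tested at the boundary). The three kinds are the default because
processed secreted products are annotated inconsistently across these
types; the set is a parameter for stricter readings. Features with unknown
coordinates (`?`) are skipped with a warning; coordinates outside the
precursor are an error, not a silent truncation.

## The noise model

Measurement error is modeled per code element as Gaussian with standard
deviation proportional to the true value: an element $x$ is observed as
$\mathcal{N}(x, (\mathrm{RSD}\cdot x)^2)$. Zero elements therefore stay
exactly zero — a residue type that is absent produces no barcode to
miscount. Negative draws (possible at RSD above ~30%) are clipped to zero,
since codes are physical abundances; this introduces a small upward bias at
extreme RSD and is deliberately documented rather than resolved by
truncated-normal sampling, which would change the variance the RSD
parameter claims.

Because the noise is relative, the process is scale-equivariant: perturbing
$\alpha x$ is distributionally $\alpha$ times perturbing $x$, so coverage
results do not depend on whether counts or normalized ratios are perturbed
(a seeded test asserts the proportionality exactly).

Monte Carlo coverage perturbs every entry's code and searches it against
the clean library — equivalent to perturbing the database once, by symmetry
of the pairwise comparison — and reports the mean of 5 independent
replicate coverages, the customary replicate count for this simulation.
Default search depth is top-1; depth is a parameter. Seed discipline: a
master seed plus (rsd-index, panel-index, replicate-index) derive
independent sub-streams through a Lehmer-style fold kept below $2^{31}$,
so any single cell of a sweep is reproducible in isolation and the caller's
RNG state is never disturbed.

## qPCR conversion

Quantification runs through a fitted standard curve, Ct $= a \log_{10}(\mathrm{copies}) + b$,
rather than the 2^−ΔCt shortcut: the two coincide at 100% amplification
efficiency, and the curve-based route stays correct when efficiency
($10^{-1/a} - 1$) departs from 1. Per channel, the mean Ct over replicate
wells is converted to copies, divided by the aliquot's fluorescence
calibration signal (the dye reports how much analyte the aliquot actually
carried through labeling and cleanup), and expressed relative to the
reference channel — Lys by convention — whose value is exactly 1 by
construction. Averaging happens at two well-defined points only: mean Ct
across wells within a run (before the nonlinear Ct→copies map, matching
how plate readouts are customarily reduced), and the arithmetic mean of
per-run ratio codes across independent runs. "Undetermined" wells mean no
amplification: a channel with no determined well maps to 0 copies, which
is how a genuinely absent residue type reads out; an undetermined
*reference* channel is an error, since no ratio can be formed.

The synthetic forward model (`simulate_qpcr_run()`) inverts this exactly —
log-normal aliquot fluorescence with unit mean scales the loaded copies,
well Cts come from the curve plus Gaussian cycle noise — so the noiseless
round trip recovers codes to 1e-9 and serves as the module's oracle.

## The synthetic proteome generator

`generate_proteome()` draws i.i.d. residues from a pinned table of average
human protein composition (the published Swiss-Prot average frequencies,
normalized to sum to 1), with lengths uniform on 50–500 and 1,000 proteins
by default — the scale used throughout the package's statistical tests.
`generate_secretome_fixture()` cuts each synthetic precursor into 1–3
contiguous chains of at least 5 residues so precursor-group collapsing is
exercised structurally.

What the generator emulates: realistic marginal residue frequencies, hence
realistic code collision rates per panel size; precursor/chain grouping.
What it does not emulate: residue autocorrelation, domain structure, length
biases of secreted peptides, homologous families (near-duplicate codes from
paralogs), or annotation noise. Passing statistical tests on this fixture
therefore demonstrates that the machinery behaves as the model predicts —
coverage monotone in panel size and search depth, degrading with RSD, more
channels more error-tolerant — not that any particular coverage percentage
transfers to a real proteome, where paralog families make codes collide
more often than i.i.d. sampling does. Real-proteome numbers should be
computed by pointing the same pipeline at a downloaded database release.

## Problem sizes and runtime choices

The statistical test suite and the acceptance script use the 1,000-protein
synthetic proteome, panels of 2–9 channels, an RSD grid of
{0.5%, 1%, 3%, 5%, 10%} on the 4- and 9-channel panels with 5 replicates,
and 10,000 draws for the noise-statistics checks: sizes chosen so the full
sweep completes in seconds while the binomial standard errors (≈1.5
percentage points at n = 1,000) are small against the effects being
asserted, with all inequality checks carried out at 2-standard-error
margins.

## Known limitations

* Labeling efficiency and off-target reactions are not modeled; measured
  codes inherit whatever bias the chemistry has.
* The error model is i.i.d. relative Gaussian per element; correlated or
  channel-specific biases are out of scope.
* The UniProt flat-text reader is a minimal parser covering the record
  types the extraction needs (ID/AC/KW/CC subcellular location/FT/SQ); it
  is not a general flat-file library.
* Search is exact and exhaustive; no indexing for databases far beyond
  proteome scale.
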