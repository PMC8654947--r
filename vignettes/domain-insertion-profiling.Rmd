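---
title: "Domain-insertion profiling: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-insertion profiling: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dipscan` analyses massively parallel domain-insertion experiments: a
library of donor motifs inserted after every residue of a recipient
protein, phenotyped by sorting cells into surface-labelled *high* and *low*
gates and sequencing each gate. This vignette explains the statistical
model behind each stage, the tunable parameters and their defaults, what
the synthetic generator does and does not emulate, and the design decisions
we made where more than one reasonable implementation exists.

## The fitness statistic

For one donor motif, one replicate and one sequencing subpool, with
per-position read counts $h_i$ (high gate) and $l_i$ (low gate) over the
$n$ insertion positions, the raw surface-expression enrichment is

$$\mathrm{score}_i \;=\;
  \ln\frac{0.5+h_i}{\sum_i (0.5+h_i)} \;-\;
  \ln\frac{0.5+l_i}{\sum_i (0.5+l_i)} .$$

The 0.5 pseudocount stabilises positions with very small counts; the
denominators sum over **all** positions of the group, so the statistic
measures a position's enrichment relative to the motif's own profile. A
consequence worth knowing: a motif effect that is *uniform across
positions* cancels exactly (if $h_i = c\,l_i$ for all $i$, every score is
0). Positions lacking reads in both gates do not qualify and are reported
as missing — explicitly `NA`, never silently zero.

Scores are anchored to an internal flexible-linker control (amino-acid
sequence AGSAGSA), whose true insertion effect defines the zero point:

$$z_{i,m,r} = \frac{\mathrm{score}_{i,m,r} - \mu_{\mathrm{ctrl}}}
                   {\sigma_{\mathrm{ctrl}}},$$

with $\mu$ and $\sigma$ the mean and sample standard deviation (ddof = 1)
of the control's raw scores within the normalisation scope. The default
scope is per replicate (one collection batch): in a design where subpools
partition the variant set the control belongs to a single subpool, so a
strictly per-subpool scope would be undefined elsewhere; the assay this
emulates collects the control library separately each sorting day to
normalise all pools, which corresponds to the per-batch scope. A
`scope = "subpool"` mode is available for designs that include the control
in every subpool. Degenerate anchors (fewer than two control scores, or
zero variance) are rejected rather than silently propagated.

Each variant's sampling error is approximated from Poisson counting,

$$SE = \sqrt{\tfrac{1}{c_h+0.5} + \tfrac{1}{c_l+0.5}
           + \tfrac{1}{T_h+0.5} + \tfrac{1}{T_l+0.5}},$$

where $T$ are the gate totals for the group (pseudocount added once to
each term). Replicates are combined per variant by a weighted average with
weights $\sqrt{M + SE_r^2}\big/\sum_r \sqrt{M + SE_r^2}$, where $M$ is the
restricted-maximum-likelihood estimate of the between-replicate variance
in the random-effects model $z_r \sim N(\theta,\, M + SE_r^2)$, obtained by
Fisher scoring (up to 50 iterations, floored at 0). Two fixed points are
contractual and tested: identical replicate scores give $M = 0$ and return
the common score; a single replicate passes through with weight 1. Note
the square-root weight — as specified — *up-weights noisier replicates*
relative to inverse-variance weighting; an inverse-variance mode
(`weighting = "inverse-variance"`) is provided for sensitivity analysis
and is off by default. $M$ is estimated per variant (position × motif)
across replicates; per-motif or per-replicate alternatives were considered
and not implemented.

Finally, motifs observed at a fraction of positions strictly greater than
`min_fraction` (default 0.8) are retained; the rest are removed and
reported.

## Insertion calling

The caller is a deliberately simple exact-match seed-and-extend: the first
`min_flank` (default 15 nt) of a read seeds against the recipient CDS and
the match is extended maximally; the junction is the first non-recipient
base (0-based CDS offset $j$), reported as insertion "after residue
$\lfloor j/3\rfloor$" with `in_frame` true iff $j \equiv 0 \pmod 3$. Two
subtleties matter in practice:

* **Junction pull-back.** When the first inserted base coincides with the
  next recipient base, maximal extension overruns the true junction (a
  ~25 % event for random sequence). The caller therefore scans placements
  back from the maximal extension (bounded slack, 12 nt) and prefers the
  longest placement at which the intervening segment matches a known motif
  (prefix, suffix, or whole motif with the recipient resuming); only if no
  placement matches is the maximal extension reported with
  `motif_id = "unknown"`.
* **Suffix anchoring.** Reads that begin inside the insert are anchored on
  the downstream motif/recipient junction by running the same algorithm in
  reversed sequence space. Both anchors are tried and a motif-identified
  placement wins over an unknown one.

Truly ambiguous reads (several equally long placements, or several motifs
matching) are refused rather than guessed. Reads are tried as given and as
their reverse complement; the matching orientation is recorded as the
call's direction. If both mates of a pair call the same (position, motif)
the call is counted once; discordant mates are both dropped. Out-of-frame
calls are tallied separately from the main count table, mirroring the
fluorescence gating that removes frameshifted variants in the assay.
Substitution errors are tolerated only outside the exact-match flanks; the
caller is built for desk-scale synthetic and low-error data, not for a
production aligner's error model.

## Biophysical properties

**Elastic network.** The anisotropic network model connects Cα atoms
within `cutoff` (default 15 Å, spring constant γ = 1, both configurable)
and eigen-decomposes the 3N×3N Hessian. A connected network has exactly
six numerically zero rigid-body modes (relative threshold 1e-8); the
builder verifies this and rejects disconnected or degenerate (e.g.
collinear or planar) geometries — note that toy "chain" fixtures must be
three-dimensional (we use a helix) because a planar bead arrangement has
no out-of-plane restoring force in an ANM. The per-residue *fluctuation
profile* is the trace of the residue's block of the Hessian pseudo-inverse
(an RMSF surrogate, normalised to mean 1); molecular-dynamics-derived RMSF
is never computed here — it can be supplied as an annotation table and the
ANM profile is the clearly labelled stand-in. The *stiffness profile*
follows the mechanical-stiffness formulation: for each residue pair the
compliance is the internal-mode sum of squared relative displacements
projected on the inter-residue direction, weighted by $1/\lambda_k$; the
effective force constant is its reciprocal and the profile is the mean
over partners. Stiffness is linear in γ and, like every structure-derived
quantity here, invariant under rigid-body transforms (fluctuations and
stiffness to 1e-8; solvent accessibility only to the sphere-sampling
resolution, about 1 %).

**Sequence windows.** Fourteen published per-residue scales (Kyte–
Doolittle hydropathy, Eisenberg hydrophobicity, Chou–Fasman propensities,
Grantham polarity, Zamyatnin volume, and so on; each documented in
`?aa_scales`) are summed over windows anchored at each insertion site —
*before* (residues $i-w+1..i$), *after* ($i+1..i+w$) and *centered*
(lengths 1, 3, 5, 7, 9, 11) — and over whole motifs plus N-/C-terminal
windows of length 1–6. Windows clipped at a terminus are summed over the
available residues and flagged as truncated rather than dropped or
NA-filled. Which residue-level table best matches each scale name used by
upstream tooling is not fully documented there; ours are standard
published tables, recorded per column in the assembled feature tables.

**Contacts, backbone, surface.** Contact density is the count of
inter-residue heavy-atom pairs within 4.5 Å (sequence separation ≥ 2) — a
distance-cutoff stand-in for SMARTS-typed contact detection, which gives
systematically different absolute values. φ/ψ dihedrals follow the IUPAC
sign convention (verified against an independent torsion implementation
and by rebuilding backbones from specified angles). Solvent-accessible
surface area uses the Shrake–Rupley sphere-point method (probe 1.4 Å, 256
points per atom; the isolated-sphere value is exact by construction),
split into polar (N/O) and nonpolar (C/S) components. Secondary-structure
flags come from a user-supplied annotation table; no DSSP-style assignment
is reimplemented.

## Classification and annotation

Motif profiles are clustered with Ward's method (`ward.D2`) on a cosine
distance computed over pairwise-complete positions, cut at three groups by
default. Positional classes come from k-means on a 2-D embedding of the
position × motif fitness matrix, with the class number chosen by majority
vote over five cluster-validity indices — silhouette, Calinski–Harabasz,
Davies–Bouldin, Dunn and the gap statistic (Tibshirani one-standard-error
rule) — each implemented in the package, with ties broken toward the
smaller k. Three choices here were genuinely open:

* **Metric.** Cosine distance is scale-invariant, which is right for motif
  *response patterns* but wrong for positional classes, which differ
  chiefly by additive fitness offsets that cosine discards (on planted
  surfaces it collapses the rigid and intermediate classes into one
  direction). Positional classification therefore defaults to Euclidean
  distance; `metric = "cosine"` remains available.
* **Embedding.** The default 2-D embedding is classical multidimensional
  scaling of the chosen metric; `embed = "umap"` runs UMAP (local
  neighbourhood `n_neighbors = 10`) through the system `python`
  (umap-learn) for users who prefer the nonlinear projection. The
  consensus-k machinery is identical either way.
* **Index space.** k-means runs on the embedding, but the four geometric
  validity indices are evaluated in the *original profile space*. Scored
  inside a 2-D embedding, any Gaussian blob drifts toward high k (all four
  indices can agree on the top of the range); scored on profiles,
  structureless data scatters the votes and the smaller-k tie rule applies,
  which is the behaviour a null dataset should produce. The gap statistic
  stays on the embedding because its uniform reference must live in the
  space being clustered.

Missing cells are imputed with the per-motif mean before embedding (the
per-motif anchor matches the z-score normalisation); a `drop` mode removes
rows over 50 % missing instead. Per-position Spearman correlations between
motif properties and fitness (pairwise-complete, minimum 30 pairs by
default) give a correlation profile that is itself clustered
(cosine/Ward, three classes). Class enrichment for annotated site sets
uses two-sided Fisher's exact tests (the implementation is
`stats::fisher.test`; the suite verifies it against full fixed-margin
enumeration) with Haldane-corrected sample odds ratios; agreement between
two labelings is Pearson's χ² with Cramér's V
$\sqrt{\chi^2/(n(\min(r,c)-1))}$. The terminal-enrichment analysis counts
productive cells (score above a threshold, default 0 = better than the
flexible-linker average) in the first/last `terminal_window` residues
(default 45) against the window-size expectation.

## The compatibility model

Features are first de-duplicated: the transitive closure of
|Pearson ρ| ≥ 0.8 defines redundancy groups, and each group keeps the
feature with the largest summed |correlation with the response| (summed
over the levels of a grouping factor when supplied — across positions for
motif features, across motifs for recipient features). The reduction is
idempotent and constant features are removed first. The model is a
regression random forest (500 trees, mtry = p/3, default tree controls;
`randomForest`) on a seeded 85/15 split, reporting held-out and
out-of-bag variance explained. Importance is *drop-and-refit*: each
feature is removed, the forest refit on the same split, and the increase
in held-out mean absolute error recorded (permutation importance exists
behind a flag for comparison; negative increases are clipped only in the
ranked report). First- and second-order accumulated local effects follow
the Apley–Zhu estimators on quantile grids (20 and 10 bins by default;
empty 2-D cells borrow the nearest non-empty cell's cross-difference and
are flagged), centred to data-weighted mean zero. Interaction strength is
Friedman's H computed from centred partial dependences on a sampled grid
(default min(500, n) points), clipped into [0, 1] with a flag on
excursions. All three estimators accept a plain prediction function, so
closed-form oracles (linear slope, additive ⇒ H ≈ 0 and flat second-order
surface, multiplicative on independent centred features ⇒ H = 1, saddle
with corner signs + − − +) are tested directly against them.

## What the generator emulates — and what it does not

The generator plants a fitness surface
$f_{im} = \alpha_{\mathrm{class}(i)} + \beta_{\mathrm{group}(m)} +
\gamma_{\mathrm{class},\mathrm{group}} + \varepsilon$, with positional
classes occupying contiguous blocks (mimicking contiguous structural
regions) and the control motif pinned at exactly 0 as the normalisation
anchor. Default effects make positional structure dominate
(rigid −3, intermediate −1, flexible +1) over motif groups
(structured −0.3, unstructured +0.3, hydrophobic −0.8), with interactions
planting the signatures seen in real insertion profiling: structured
motifs gain at flexible termini (+1.2), hydrophobic motifs are tolerated
in rigid buried regions (+0.8), unstructured motifs are penalised there
(−0.8); noise sd 0.5. Recipient dominance is not merely a convenience: the
enrichment statistic's within-motif normalisation cancels uniform motif
effects by construction, so a surface dominated by motif main effects
could not be recovered by this statistic from any sequencing depth — a
property of the estimator, not of the generator.

Sorting is a logistic gate: $P(\mathrm{high}) = \mathrm{logit}^{-1}
(a f + b)$ with slope 1 and intercept 0 by default — the minimal monotone
link for a two-gate sort. Cells are allocated per gate, replicate and
subpool by a multinomial over variants (uniform library abundance), reads
by a single multinomial over sorted cells. Dropout removes a configurable
fraction of library variants per replicate (default 5 %), sparing the
control, which the emulated assay collects separately at high coverage.
Junction-spanning read pairs are cut from fragments positioned so the
first mate always spans a junction with at least `flank` nucleotides on
both sides; read names encode the generating variant so callers can be
scored exactly.

Deliberately *not* modelled: PCR jackpotting and chimeras (reads are one
multinomial; a dispersion knob could be added, default off),
sequencing-quality profiles (constant quality strings), instrument error
beyond uniform substitutions, the negative-selection step used to remove
unrecombined cells, and abundance skew across the library. Passing tests
on this generator therefore demonstrates the *estimators'* correctness
and calibration under idealised noise, not robustness to library-prep
artefacts in real data.

## Numerical choices and problem sizes

Fisher scoring for $M$ stops early when the step falls below 1e-14
(relative), always within the 50-iteration cap; the two-replicate case is
checked against the closed form and multi-replicate cases against an
independent REML implementation to 1e-4. The eigenvalue zero-mode
threshold is 1e-8 relative to the largest eigenvalue. k-means uses 20
restarts per k, seeded per k for determinism; the gap statistic uses 25
uniform reference sets. The test-and-acceptance workloads use 50 × 40
libraries at 10⁵ reads per gate for recovery, 10⁴ read pairs for calling,
1 000 random count tables for oracle agreement, and 5 seeds for
classification and model-recovery checks — sizes at which every
contractual margin is comfortably resolved on a laptop-class machine. The
model-recovery benchmark gives its four generating features effect sizes
of comparable magnitude, each well above the response noise, so that it
measures the importance estimator rather than feature-level
signal-to-noise luck.

## Known limitations

Exact-match calling cannot place junctions whose recipient flank is
shorter than `min_flank` on both ends of the read (such pairs are dropped,
not mis-called). The as-printed REML weight is kept for fidelity even
though inverse-variance weighting is statistically preferable. Contact
counts are not comparable in absolute value to typed-contact webserver
output. SASA rigid-body invariance is limited by sphere sampling. The
UMAP path requires a python with umap-learn on the PATH and is not
exercised by the default test run. Real-data features the generator does
not emulate are listed above; conclusions about robustness to them require
real libraries.
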