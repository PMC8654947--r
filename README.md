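# dipscan

Analysis toolkit for **massively parallel domain-insertion profiling** of
membrane proteins read out by a two-gate surface-expression sort-seq assay.
In this kind of experiment, a library of polypeptide motifs (donors) is
inserted after every residue of a recipient protein (an ion channel such as
an inward-rectifier K⁺ channel), cells carrying single variants are sorted
into surface-labelled **high** and **low** FACS gates, and each gate is
deep-sequenced. The per-variant log-enrichment between gates, normalised to
an internal flexible-linker control, is the variant's *surface-expression
fitness* — a readout of whether the recombined protein still folds,
assembles and traffics.

`dipscan` implements the full downstream analysis:

* **Insertion calling** — a seed-and-extend junction caller for paired-end
  reads spanning motif/recipient junctions (position, orientation, reading
  frame; paired duplicates collapsed, discordant mates dropped).
* **Fitness statistic** — per-group raw enrichment
  `ln[(0.5+h_i)/Σ(0.5+h_i)] − ln[(0.5+l_i)/Σ(0.5+l_i)]`, z-scored to the
  AGSAGSA flexible-linker control, with Poisson standard errors
  `√(1/(c_h+0.5) + 1/(c_l+0.5) + 1/(T_h+0.5) + 1/(T_l+0.5))` and replicate
  combination weighted by `√(M+SE²)`, where `M` is a per-variant REML
  (Fisher-scoring) estimate of the between-replicate variance; motifs
  observed at ≤ 80 % of positions are filtered out.
* **Biophysical properties** — anisotropic-network-model (ANM) stiffness and
  fluctuation profiles, windowed sums of 14 published amino-acid scales,
  heavy-atom contact counts, φ/ψ dihedrals, and Shrake–Rupley solvent
  accessibility, assembled into recipient and motif feature tables.
* **Classification** — cosine/Ward motif clustering; positional classes via
  a 2-D embedding plus k-means with the class number chosen by majority
  vote over five cluster-validity indices; per-position property–fitness
  correlation profiles; Fisher's-exact class enrichment; Cramér's V class
  agreement; terminal-vs-middle productive-insertion fractions.
* **Compatibility model** — correlation-based feature redundancy reduction,
  a 500-tree regression random forest on an 85/15 split, drop-and-refit
  feature importance, first- and second-order accumulated local effects
  (ALE), and Friedman's H pairwise interaction strength.
* **Synthetic sort-seq generator** — libraries, planted fitness surfaces,
  gated cell/read counts, junction-spanning paired reads, and coupled
  property tables, so every stage is testable without external data.

## Worked example

Simulate a 50-position × 40-motif library sorted to two gates at 10⁵ reads
per gate in two replicates, score it, and classify the insertion positions:

```r
library(dipscan)

design <- make_design(recipient_length = 50, n_motifs = 40, seed = 1)
design
#> <dip_design> 50 positions x 40 motifs (+control) = 2050 variants, 1 subpool(s)

truth  <- simulate_true_fitness(design, seed = 2)
counts <- simulate_sort_counts(design, truth,
                               sort_model(reads_per_gate = 1e5, replicates = 2),
                               seed = 3)
scores <- score_counts(counts, control_motif = design$control_motif_id)
scores
#> <dip_scores> 50 positions x 41 motifs (0 motifs removed by filter)
#>   missing cells: 0.7%

v   <- subset(design$variants, motif_id != design$control_motif_id)
est <- scores$fitness[cbind(as.character(v$position), v$motif_id)]
tru <- truth$fitness[cbind(as.character(v$position), v$motif_id)]
cor(tru, est, method = "spearman", use = "complete.obs")
#> [1] 0.975

fm      <- scores$fitness[, colnames(scores$fitness) != design$control_motif_id]
classes <- position_classes(fm, seed = 4)
classes$k
#> [1] 3
mclust::adjustedRandIndex(classes$labels, truth$position_class)
#> [1] 1
```

The Spearman correlation of 0.975 says the combined z-scores reconstruct
the planted fitness surface almost perfectly at this depth; the positional
classifier finds exactly the three planted structural classes (rigid /
intermediate / flexible; adjusted Rand index 1), with all five validity
indices voting for k = 3.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/dipscan-cli.R` with `simulate`, `score` and `annotate`
subcommands.

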