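# beigesig

Classifying adipose tissue by marker-set concordance: are a tissue panel's
expression profiles those of classical (interscapular-type) brown
adipocytes, or of inducible beige/brite cells?

Classical brown and beige adipocytes both express UCP1 and look alike, but
arise from different lineages and carry distinct transcriptional
signatures. `beigesig` implements, as a tested R pipeline, the two-stage
procedure for settling a tissue's identity from expression data:

1. **Marker discovery.** From a three-condition experiment (white
   adipocytes, rosiglitazone-induced beige cells, classical brown
   adipocytes, replicated cultures), genes passing a differential-expression
   filter (fold change ≥ 2 and unpaired t-test *P* ≤ 0.05 in some pairwise
   contrast) are classified into four enrichment groups: white-selective,
   beige-selective, classical-brown-selective, and "common brown" genes
   shared by both thermogenic types.
2. **Marker-set concordance.** On a tissue panel (e.g. qRT-PCR relative
   expression from multiple human fat depots, quantified here by the
   ΔΔCt method with TBP as endogenous control), the Pearson correlation
   *r<sub>i</sub>* between an anchor gene (a common brown-fat regulator,
   PRDM16/PGC1α role) and each member *i* of a marker set is integrated
   through Fisher's z,

   z<sub>i</sub> = atanh(r<sub>i</sub>),  z̄ = Σ w<sub>i</sub> z<sub>i</sub> / Σ w<sub>i</sub> with w<sub>i</sub> = n<sub>i</sub> − 3,  r̄ = tanh(z̄),

   giving a **gene-set correlation coefficient** r̄ per set. Two competing
   sets are compared by a Z-test on their integrated z-scores,
   Z = (z̄₁ − z̄₂) / √(SE₁² + SE₂²), and the set with the higher r̄ wins.
   Genes with too many Tukey-whisker outliers (beyond quartile ± 1.5·IQR)
   are screened out first, the UCP1 situation; average-linkage clustering
   on the distance 1 − r and scaled heatmap/ellipse exports summarize the
   panel.

A seeded synthetic-data module generates both study designs with ground
truth — planted marker groups for stage 1, and a one-factor "beige
activity" model for stage 2 in which beige-selective genes and the anchors
share a latent factor while classical markers sit at the detection floor —
so the entire pipeline is testable without any external dataset.

The package is aimed at transcriptomics analysts who want a reproducible,
unit-tested version of this classification logic rather than a one-off
script: every statistic above is an exported, documented function.

## Worked example

```r
library(beigesig)

cfg <- tissue_panel_sim_config(
  n_tissues = 15,
  marker_sets = list(beige = sprintf("BG%02d", 1:8),
                     classical = sprintf("CL%02d", 1:8)),
  anchor_genes = c("ANCH1", "ANCH2"),
  beige_loading = 0.9, noise_sd = 0.3, seed = 202
)
pan <- generate_tissue_panel(cfg)

gb <- gene_set_correlation("ANCH1", cfg$marker_sets$beige, pan$matrix,
                           se_mode = "independent", set_label = "beige")
gc <- gene_set_correlation("ANCH1", cfg$marker_sets$classical, pan$matrix,
                           se_mode = "independent", set_label = "classical")
compare_set_correlations(gb, gc)
#> Concordance verdict for anchor ANCH1:
#>   beige r_bar = 0.9057 vs classical r_bar = 0.0489
#>   Z = 10.076, two-sided p = 7.075e-24 (independent SE) -> winner: beige
```

The anchor's integrated correlation with the beige set (r̄ = 0.91) far
exceeds that with the classical set (r̄ = 0.05): this synthetic panel —
built so that one latent factor drives beige genes and anchors while
classical genes idle at the floor — is called **beige**, and the Z-test
says the difference is far beyond chance. The `"conservative"` SE mode
(the default, `SE = 1/√(n−3)` per set) treats each set as a single
correlated measurement and gives the cautious version of the same verdict
(Z = 3.56, p = 3.7e-4 on this panel).

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
whole study flow on synthetic data, writing tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_data.R` | simulate the three-condition profiles and the tissue panel |
| `02_discover_markers.R` | DE filter + four-group classification, recovery vs ground truth, overlap arithmetic |
| `03_qpcr_validation.R` | ΔΔCt quantification round-trip at zero and realistic Ct noise |
| `04_tissue_concordance.R` | outlier screen, correlation matrix, dendrogram, verdicts, 200-panel win rate |
| `05_report_exports.R` | heatmap/ellipse exports and a manifest-logged pipeline rerun |

Run them in order from the repository root: `Rscript analysis/01_simulate_data.R` etc.

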