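#!/usr/bin/env Rscript
# Simulate the two synthetic datasets every later stage consumes:
#  (a) three adipocyte culture conditions (white, rosiglitazone-induced
#      beige, classical brown) with planted marker groups, and
#  (b) a human-like multi-depot tissue panel in which one latent "beige
#      activity" factor drives beige-selective genes and the common brown
#      anchors, while classical-brown-selective genes sit near the
#      detection floor.
# Writes expression/metadata TSVs, marker-set GMT and ground-truth JSON
# under results/data/.

suppressMessages(library(beigesig))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

profiles_cfg <- cell_type_sim_config(
  n_genes = 2000, n_replicates = 3,
  planted_groups = c(WHITE = 30, BEIGE_ONLY = 140, COMMON_BROWN = 30,
                     CLASSICAL_ONLY = 290),
  fold_effect = 4, noise_cv = 0.2, seed = 101
)
profiles <- generate_cell_type_profiles(profiles_cfg)
write_expression_tsv(profiles$matrix,
                     file.path(out, "profiles_expression.tsv"),
                     file.path(out, "profiles_metadata.tsv"))
write_ground_truth_json(profiles$truth, file.path(out, "profiles_truth.json"))
cat(sprintf("cell-type profiles: %d genes x %d samples, %d planted markers\n",
            nrow(exprs_of(profiles$matrix)), ncol(exprs_of(profiles$matrix)),
            sum(profiles$truth$gene_labels != "UNCLASSIFIED")))

panel_cfg <- tissue_panel_sim_config(
  n_tissues = 15,
  marker_sets = list(beige = sprintf("BG%02d", 1:8),
                     classical = sprintf("CL%02d", 1:8)),
  anchor_genes = c("ANCH1", "ANCH2"),
  beige_loading = 0.9, noise_sd = 0.3, seed = 202
)
panel <- generate_tissue_panel(panel_cfg)
write_expression_tsv(panel$matrix,
                     file.path(out, "panel_expression.tsv"),
                     file.path(out, "panel_metadata.tsv"))
write_gmt(panel_cfg$marker_sets, file.path(out, "panel_marker_sets.gmt"))
writeLines(panel_cfg$anchor_genes, file.path(out, "panel_anchors.txt"))
write_ground_truth_json(panel$truth, file.path(out, "panel_truth.json"))
m <- exprs_of(panel$matrix)
cat(sprintf("tissue panel: %d genes x %d tissues; classical-set median %.3g vs beige-set median %.3g (near-floor as designed)\n",
            nrow(m), ncol(m),
            median(m[panel_cfg$marker_sets$classical, ]),
            median(m[panel_cfg$marker_sets$beige, ])))
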