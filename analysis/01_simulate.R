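#!/usr/bin/env Rscript
# Stage 1 — generate the study's synthetic inputs with ground-truth manifests.
#
# One seeded scenario covering every downstream stage: an IC50 panel with a
# planted resistant subgroup and secondary drug, single-agent dose-response
# curves, a fixed-ratio combination with a planted CI, pre/post single-cell
# counts with a PSAT1-high cluster eroded by treatment, and a patient cohort
# with a reversible recurrence signature.

suppressPackageStartupMessages(library(doublehit))
seed <- 101
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## pharmacogenomic panel -----------------------------------------------------
pgx <- simulate_pgx_panel(seed = seed)
write_panel(pgx$panel, file.path(out, "panel.csv"))
write.csv(pgx$panel$annotations, file.path(out, "cell_lines.csv"),
          row.names = FALSE)
write.csv(pgx$manifest$drug_annotations, file.path(out, "drugs.csv"),
          row.names = FALSE)

## dose-response + combination ----------------------------------------------
doses1 <- 10^seq(-0.5, 2, length.out = 8)   # secondary drug, nM
doses2 <- doses1 * 2.5                       # taxane-like primary, nM
cv1 <- simulate_median_effect_curve(10, 1.5, doses1, fa_noise_sd = 0.02,
                                    seed = seed, drug_id = "secdrug")
cv2 <- simulate_median_effect_curve(25, 1.0, doses2, fa_noise_sd = 0.02,
                                    seed = seed + 1, drug_id = "taxane")
combo <- simulate_combination(list(Dm = 10, m = 1.5), list(Dm = 25, m = 1.0),
                              data.frame(d1 = c(1, 2, 4, 8),
                                         d2 = c(2.5, 5, 10, 20)),
                              CI_true = 0.25, fa_noise_sd = 0.02, seed = seed)
write.csv(rbind(as.data.frame(cv1)[, 1:2] |> cbind(drug_id = "secdrug"),
                as.data.frame(cv2)[, 1:2] |> cbind(drug_id = "taxane")),
          file.path(out, "single_agent.csv"), row.names = FALSE)
write.csv(as.data.frame(combo$combo), file.path(out, "combination.csv"),
          row.names = FALSE)

## single-cell pre/post ------------------------------------------------------
sc <- simulate_sc_counts(seed = seed)
write_cell_counts(sc$pre, file.path(out, "sc_pre"))
write_cell_counts(sc$post, file.path(out, "sc_post"))

## patient cohort + treatment experiment -------------------------------------
co <- simulate_cohort(seed = seed)
write.csv(co$patient$expr, file.path(out, "cohort_expr.csv"))
write.csv(data.frame(patient = names(co$patient$recurrent),
                     recurrent = co$patient$recurrent),
          file.path(out, "cohort_labels.csv"), row.names = FALSE)
write.csv(co$treatment$pre, file.path(out, "treatment_pre.csv"))
write.csv(co$treatment$post, file.path(out, "treatment_post.csv"))

## ground truth --------------------------------------------------------------
write_manifest(list(
  seed = seed,
  panel = pgx$manifest[c("primary_drug", "planted_secdrugs",
                         "resistant_lines")],
  combination = combo$manifest[c("CI_true", "fa_true")],
  single_agent_truth = list(secdrug = list(Dm = 10, m = 1.5),
                            taxane = list(Dm = 25, m = 1.0)),
  sc = sc$manifest[c("clusters", "eroded_cluster", "prop_pre", "prop_post")],
  cohort = co$manifest[c("signature_genes", "overlap", "effect_log2")]
), file.path(out, "manifest.json"))

cat(sprintf(
  "simulated: %d x %d IC50 panel (planted secDrug %s, %d resistant lines),\n  combination CI_true = 0.25, sc pre/post with eroded cluster '%s',\n  cohort of %d patients (%d recurrent)\n",
  nrow(pgx$panel$ic50), ncol(pgx$panel$ic50),
  pgx$manifest$planted_secdrugs[1], length(pgx$manifest$resistant_lines),
  sc$manifest$eroded_cluster, length(co$patient$recurrent),
  sum(co$patient$recurrent)))
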