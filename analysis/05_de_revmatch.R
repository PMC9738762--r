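#!/usr/bin/env Rscript
# Stage 5 — differential expression and reverse signature matching.
#
# Wilcoxon rank-sum DE on the patient cohort (recurrent vs non-recurrent)
# and on the treatment experiment (post vs pre), then reverse-matching:
# genes the disease pushes up that treatment pushes back down.

suppressPackageStartupMessages(library(doublehit))

expr <- as.matrix(read.csv("results/sim/cohort_expr.csv", row.names = 1,
                           check.names = FALSE))
labels <- read.csv("results/sim/cohort_labels.csv")
pre <- as.matrix(read.csv("results/sim/treatment_pre.csv", row.names = 1,
                          check.names = FALSE))
post <- as.matrix(read.csv("results/sim/treatment_post.csv", row.names = 1,
                           check.names = FALSE))
truth <- read_manifest("results/sim/manifest.json")

rec <- labels$patient[labels$recurrent]
de_patient <- differential_expression(expr[, rec],
                                      expr[, setdiff(colnames(expr), rec)])
de_treat <- differential_expression(post, pre)
write_tsv(as.data.frame(de_patient), "results/de_patient.tsv")
write_tsv(as.data.frame(de_treat), "results/de_treatment.tsv")
cat(sprintf("significant genes: %d (cohort), %d (treatment)\n",
            sum(de_patient$significant), sum(de_treat$significant)))

rm_res <- reverse_match(de_patient, de_treat)
print(rm_res)
write_tsv(rm_res$matches, "results/reverse_match.tsv")
write_manifest(list(summary = rm_res$summary, n_shared = rm_res$n_shared),
               "results/reverse_match_summary.json")

recovered <- intersect(rm_res$matches$gene, truth$cohort$overlap)
cat(sprintf("recovered %d of %d planted reversible genes (headline trio: %s)\n",
            length(recovered), length(truth$cohort$overlap),
            paste(intersect(c("LTB4R", "IFITM3", "TMEM120B"),
                            rm_res$matches$gene), collapse = ", ")))
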