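#!/usr/bin/env Rscript
# Stage 4 — single-cell double-hit screen and cluster-erosion detection.
#
# Scores the EMT, stemness and NAD+ salvage programs per subclone cluster,
# fuses the top-ranked drugs with their target-pathway coverage in the
# resistant/stem-like clusters into double-hit scores, and tests which
# clusters erode after treatment.

suppressPackageStartupMessages(library(doublehit))

pre <- normalize_counts(read_cell_counts("results/sim/sc_pre"))
post <- read_cell_counts("results/sim/sc_post")
rk <- read.delim("results/secdrug_ranking.tsv")
class(rk) <- c("secdrug_ranking", "data.frame")
truth <- read_manifest("results/sim/manifest.json")

programs <- default_programs()
screens_by_program <- lapply(programs, function(p) score_program(pre, p))
scores <- do.call(rbind, lapply(names(screens_by_program), function(nm) {
  cbind(program = nm, as.data.frame(screens_by_program[[nm]]))
}))
write_tsv(scores, "results/subclone_scores.tsv")

# clusters of concern: maximal-scoring cluster of each aggressiveness program
flagged <- unique(vapply(screens_by_program[c("emt", "stemness",
                                              "nad_salvage")],
                         function(s) s$cluster[which.max(s$mean_score)],
                         character(1)))
cat("flagged clusters:", paste(flagged, collapse = ", "), "\n")

# target-pathway screen per ranked drug: the NAMPT-targeting candidate maps
# to the NAD+ salvage program; others have no pathway program in this
# scenario and drop out of the double-hit table
nampt_drugs <- rk$drug_id[!is.na(rk$target) & rk$target == "NAMPT"]
screens <- stats::setNames(
  rep(list(screens_by_program$nad_salvage), length(nampt_drugs)), nampt_drugs)
dh <- double_hit(rk, screens, flagged_clusters = flagged)
write_tsv(dh, "results/double_hit.tsv")
cat(sprintf("top double-hit drug: %s (rank score %.2f x coverage %.2f = %.2f)\n",
            dh$drug_id[1], dh$secdrug_rank_score[1], dh$target_coverage[1],
            dh$double_hit[1]))

erosion <- detect_cluster_erosion(pre, post)
write_tsv(erosion, "results/cluster_erosion.tsv")
print(erosion)
cat(sprintf("eroded cluster(s): %s (planted: %s)\n",
            paste(erosion$cluster[erosion$eroded], collapse = ", "),
            truth$sc$eroded_cluster))
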