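#' Simulate a drug x cell-line IC50 panel with a planted secondary drug
#'
#' Emulates the shape of a large pharmacogenomic screen. Per drug k, log10
#' IC50 is Normal(mu_k, sigma) with mu_k drawn uniformly in [1, 3] (10 nM to
#' 1 uM medians). A resistant subgroup of lines is planted: the primary
#' drug's log10 IC50 is shifted by `+shift_log10` there (they resist the
#' primary drug), while each planted secondary drug is shifted by
#' `planted_shift` (default -1: one decade more potent in exactly the
#' resistant lines). Entries go missing uniformly at `missing_rate`. Tissue
#' annotations are drawn from genitourinary labels. The planted secondary
#' drugs are annotated with the NAD+ salvage pathway (NAMPT) target, mirroring
#' an FK866-style hit; filler drugs get filler targets.
#'
#' @param n_lines,K_drugs panel dimensions.
#' @param resistant_fraction fraction of lines in the resistant subgroup.
#' @param shift_log10 primary-drug log10 shift in resistant lines.
#' @param n_planted_secdrugs number of planted secondary drugs.
#' @param missing_rate probability an entry is missing.
#' @param sigma per-drug log10 IC50 standard deviation.
#' @param planted_shift log10 shift of planted drugs in resistant lines.
#' @param seed integer RNG seed.
#' @return list with `panel` (a [dose_response_panel()]) and `manifest`
#'   (seed, `primary_drug`, `planted_secdrugs`, `resistant_lines`,
#'   `drug_annotations`).
#' @export
simulate_pgx_panel <- function(n_lines = 100, K_drugs = 30,
                               resistant_fraction = 0.2, shift_log10 = 1.5,
                               n_planted_secdrugs = 1, missing_rate = 0.05,
                               sigma = 0.3, planted_shift = -1.0, seed = 1L) {
  stopifnot(resistant_fraction > 0, resistant_fraction < 1,
            n_planted_secdrugs < K_drugs - 1, missing_rate >= 0,
            missing_rate < 1, shift_log10 > 0)
  withr_seed(seed, {
    drug_ids <- c("primary", sprintf("cand%02d", seq_len(K_drugs - 1)))
    line_ids <- sprintf("line%03d", seq_len(n_lines))
    n_res <- round(resistant_fraction * n_lines)
    resistant <- sort(sample(line_ids, n_res))
    planted <- sort(sample(drug_ids[-1], n_planted_secdrugs))

    mu <- stats::runif(K_drugs, 1, 3)
    m <- matrix(stats::rnorm(K_drugs * n_lines, mu, sigma),
                K_drugs, n_lines, dimnames = list(drug_ids, line_ids))
    is_res <- line_ids %in% resistant
    m["primary", is_res] <- m["primary", is_res] + shift_log10
    for (d in planted) m[d, is_res] <- m[d, is_res] + planted_shift
    ic50 <- 10^m
    if (missing_rate > 0) {
      ic50[stats::runif(length(ic50)) < missing_rate] <- NA_real_
    }
    tissues <- c("prostate", "breast", "ovary", "cervix", "endometrium")
    ann <- data.frame(cell_line_id = line_ids,
                      tissue = sample(tissues, n_lines, replace = TRUE),
                      subtype = NA_character_, stringsAsFactors = FALSE)
    drug_ann <- data.frame(
      drug_id = drug_ids,
      target = ifelse(drug_ids %in% planted, "NAMPT",
                      paste0("TGT_", drug_ids)),
      target_pathway = ifelse(drug_ids %in% planted,
                              "NAD+ salvage pathway",
                              paste0("pathway_", drug_ids)),
      stringsAsFactors = FALSE
    )
    list(
      panel = dose_response_panel(ic50, annotations = ann),
      manifest = list(seed = seed, primary_drug = "primary",
                      planted_secdrugs = planted,
                      resistant_lines = resistant,
                      drug_annotations = drug_ann)
    )
  })
}

#' Simulate a 4PL cytotoxicity curve
#'
#' Percent survival from the variable-slope sigmoid
#' `S(D) = bottom + (top - bottom)/(1 + (D/ic50)^hill)` plus Gaussian noise in
#' percentage points.
#'
#' @param bottom,top,ic50,hill true parameters (`ic50` in nM).
#' @param doses non-zero concentrations (nM).
#' @param noise_sd additive noise sd in percent-survival units.
#' @param replicates replicate count per dose.
#' @param seed RNG seed.
#' @param drug_id identifier attached to the curve.
#' @return a `cytotoxicity_curve`.
#' @export
simulate_4pl_curve <- function(bottom = 0, top = 100, ic50 = 50, hill = 1.2,
                               doses = 10^seq(-1, 4, length.out = 8),
                               noise_sd = 0, replicates = 1L, seed = 1L,
                               drug_id = NA_character_) {
  withr_seed(seed, {
    D <- rep(doses, each = replicates)
    y <- fourpl_value(D, bottom, top, ic50, hill)
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    cytotoxicity_curve(D, y, replicate = rep(seq_len(replicates),
                                             times = length(doses)),
                       drug_id = drug_id)
  })
}

#' Simulate a single-agent curve from the median-effect model
#'
#' `fa(D) = (D/Dm)^m / (1 + (D/Dm)^m)`, with optional Gaussian noise on fa
#' (clipped inside `(epsilon, 1 - epsilon)`); survival = 100 (1 - fa).
#'
#' @param Dm,m true median-effect dose (nM) and slope.
#' @param doses non-zero concentrations (nM).
#' @param fa_noise_sd noise sd on the fa scale.
#' @param epsilon clipping bound.
#' @param seed RNG seed.
#' @param drug_id identifier attached to the curve.
#' @return a `cytotoxicity_curve`.
#' @export
simulate_median_effect_curve <- function(Dm, m, doses, fa_noise_sd = 0,
                                         epsilon = 0.005, seed = 1L,
                                         drug_id = NA_character_) {
  withr_seed(seed, {
    fa <- (doses / Dm)^m / (1 + (doses / Dm)^m)
    if (fa_noise_sd > 0) {
      fa <- pmin(pmax(fa + stats::rnorm(length(fa), 0, fa_noise_sd),
                      epsilon), 1 - epsilon)
    }
    cytotoxicity_curve(doses, 100 * (1 - fa), drug_id = drug_id)
  })
}

#' Simulate combination measurements with a planted combination index
#'
#' Inverts the combination-index equation: for each dose pair the generator
#' solves `d1/Dx1(fa) + d2/Dx2(fa) = CI_true` for fa by bisection (the left
#' side is strictly decreasing in fa, so the root is unique), then adds
#' Gaussian noise on fa clipped to `(epsilon, 1 - epsilon)`. Pairs whose CI
#' cannot be reached inside the bracket are rejected with a message.
#'
#' @param fit1_true,fit2_true true single-agent parameters: lists (or
#'   `median_effect_fit`s) with `Dm` and `m`.
#' @param dose_pairs `data.frame` with columns `d1`, `d2` (nM), at least one
#'   positive per pair.
#' @param CI_true planted combination index (> 0).
#' @param fa_noise_sd observation noise on fa.
#' @param epsilon bracket bound for the bisection and clipping.
#' @param seed RNG seed.
#' @param tol bisection tolerance on fa.
#' @return list with `combo` (a [combination_measurement()]) and `manifest`
#'   (`CI_true`, `fa_true` per retained pair, rejected pair indices).
#' @export
simulate_combination <- function(fit1_true, fit2_true, dose_pairs,
                                 CI_true, fa_noise_sd = 0, epsilon = 0.005,
                                 seed = 1L, tol = 1e-10) {
  stopifnot(CI_true > 0, all(c("d1", "d2") %in% names(dose_pairs)))
  ci_at <- function(fa, d1, d2) {
    d1 / (fit1_true$Dm * (fa / (1 - fa))^(1 / fit1_true$m)) +
      d2 / (fit2_true$Dm * (fa / (1 - fa))^(1 / fit2_true$m)) - CI_true
  }
  fa_true <- rep(NA_real_, nrow(dose_pairs))
  for (i in seq_len(nrow(dose_pairs))) {
    d1 <- dose_pairs$d1[i]; d2 <- dose_pairs$d2[i]
    lo <- epsilon; hi <- 1 - epsilon
    if (ci_at(lo, d1, d2) < 0 || ci_at(hi, d1, d2) > 0) {
      message(sprintf("pair %d (d1=%g, d2=%g) rejected: CI %g unreachable",
                      i, d1, d2, CI_true))
      next
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (ci_at(mid, d1, d2) > 0) lo <- mid else hi <- mid
    }
    fa_true[i] <- (lo + hi) / 2
  }
  keep <- !is.na(fa_true)
  if (!any(keep)) stop("no dose pair can realise the requested CI")
  fa_obs <- withr_seed(seed, {
    fa <- fa_true[keep]
    if (fa_noise_sd > 0) {
      fa <- pmin(pmax(fa + stats::rnorm(length(fa), 0, fa_noise_sd),
                      epsilon), 1 - epsilon)
    }
    fa
  })
  list(
    combo = combination_measurement(dose_pairs$d1[keep], dose_pairs$d2[keep],
                                    fa_obs, fixed_ratio = TRUE),
    manifest = list(seed = seed, CI_true = CI_true, fa_true = fa_true[keep],
                    rejected = which(!keep))
  )
}

#' Draw per-cell cluster labels from pre/post compositions
#'
#' The composition layer of the single-cell generator, exposed on its own:
#' pre-treatment labels follow `prop_pre`; post-treatment labels follow the
#' eroded composition in which `eroded_cluster` drops to `post_fraction` and
#' the remaining clusters scale up proportionally. With `eroded_cluster =
#' NULL` pre and post compositions are equal in expectation.
#'
#' @param n_cells cells per condition.
#' @param prop_pre named pre-treatment cluster proportions (sum 1).
#' @param eroded_cluster cluster to erode, or `NULL` for the null scenario.
#' @param post_fraction the eroded cluster's post-treatment proportion.
#' @param seed RNG seed.
#' @return list with `pre`, `post` (character label vectors) and `prop_post`.
#' @export
simulate_cluster_labels <- function(n_cells, prop_pre, eroded_cluster = NULL,
                                    post_fraction = 0.01, seed = 1L) {
  stopifnot(abs(sum(prop_pre) - 1) < 1e-8, !is.null(names(prop_pre)))
  prop_post <- prop_pre
  if (!is.null(eroded_cluster)) {
    stopifnot(eroded_cluster %in% names(prop_pre))
    rest <- setdiff(names(prop_pre), eroded_cluster)
    prop_post[eroded_cluster] <- post_fraction
    prop_post[rest] <- prop_pre[rest] / sum(prop_pre[rest]) *
      (1 - post_fraction)
  }
  withr_seed(seed, {
    list(pre = sample(names(prop_pre), n_cells, TRUE, prop_pre),
         post = sample(names(prop_post), n_cells, TRUE, prop_post),
         prop_post = prop_post)
  })
}

#' Simulate pre/post single-cell count matrices with planted subclones
#'
#' Negative-binomial counts with cluster-specific marker programs: each
#' cluster's program genes are elevated (up) or depressed (down) by
#' `program_lfc` natural-log-fold units relative to a shared baseline gene
#' abundance profile. Library depth is LogNormal(log(depth_mean), 0.3) —
#' typical droplet magnitudes. The default scenario carries a bulk cluster
#' plus EMT-high, stemness-high and PSAT1-high (NAD+ salvage) subclones, and
#' the post-treatment condition erodes the PSAT1-high cluster from its
#' pre-treatment share down to `post_fraction` (default 20% -> 1%),
#' emulating the loss of a target-pathway-high subclone under treatment.
#'
#' @param n_cells_per_cluster named integer vector: pre-treatment cells per
#'   cluster (>= 2 clusters).
#' @param cluster_programs named list cluster -> [gene_program()] (clusters
#'   may be absent = no program; default: EMT/stemness/NAD-salvage programs).
#' @param program_lfc log-fold elevation of program genes (default 2).
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param depth_mean mean library size.
#' @param eroded_cluster cluster eroded post-treatment, or `NULL`; default
#'   the PSAT1-high cluster.
#' @param post_fraction eroded cluster's post share.
#' @param n_filler_genes filler genes (G0001...) beyond the program genes.
#' @param seed RNG seed.
#' @return list with `pre`, `post` ([cell_counts()]) and `manifest`.
#' @export
simulate_sc_counts <- function(
    n_cells_per_cluster = c(bulk = 300, emt = 150, stemness = 150,
                            psat1_high = 200),
    cluster_programs = NULL, program_lfc = 2, nb_dispersion = 0.5,
    depth_mean = 5000, eroded_cluster = "psat1_high", post_fraction = 0.01,
    n_filler_genes = 200, seed = 1L) {
  stopifnot(length(n_cells_per_cluster) >= 2,
            !is.null(names(n_cells_per_cluster)))
  if (is.null(cluster_programs)) {
    pr <- default_programs()
    cluster_programs <- list(emt = pr$emt, stemness = pr$stemness,
                             psat1_high = pr$nad_salvage)
    cluster_programs <- cluster_programs[
      intersect(names(cluster_programs), names(n_cells_per_cluster))]
  }
  clusters <- names(n_cells_per_cluster)
  prog_genes <- unique(unlist(lapply(cluster_programs, `[[`, "genes")))
  genes <- c(prog_genes, sprintf("G%04d", seq_len(n_filler_genes)))

  withr_seed(seed, {
    base <- stats::rgamma(length(genes), shape = 2, rate = 2)
    names(base) <- genes
    # marker genes sit near dropout outside their own subclone
    base[prog_genes] <- base[prog_genes] * 0.15
    cluster_frac <- sapply(clusters, function(k) {
      w <- base
      prg <- cluster_programs[[k]]
      if (!is.null(prg)) {
        lfc <- ifelse(prg$direction == "up", program_lfc, -program_lfc)
        w[prg$genes] <- w[prg$genes] * exp(lfc)
      }
      w / sum(w)
    })

    n_total <- sum(n_cells_per_cluster)
    pre_labels <- rep(clusters, n_cells_per_cluster)
    prop_pre <- n_cells_per_cluster / n_total
    if (!is.null(eroded_cluster)) {
      comp <- simulate_cluster_labels(n_total, prop_pre, eroded_cluster,
                                      post_fraction,
                                      seed = sample.int(2^31 - 1, 1))
      post_labels <- comp$post
      prop_post <- comp$prop_post
    } else {
      post_labels <- sample(clusters, n_total, TRUE, prop_pre)
      prop_post <- prop_pre
    }

    draw <- function(labels, prefix) {
      n <- length(labels)
      depth <- stats::rlnorm(n, log(depth_mean), 0.3)
      mu <- cluster_frac[, labels, drop = FALSE] *
        rep(depth, each = length(genes))
      cnt <- matrix(stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / nb_dispersion),
                    length(genes), n,
                    dimnames = list(genes, sprintf("%s_%05d", prefix,
                                                   seq_len(n))))
      cell_counts(cnt, labels,
                  condition = if (prefix == "pre") "pre" else "post")
    }
    list(
      pre = draw(pre_labels, "pre"),
      post = draw(post_labels, "post"),
      manifest = list(seed = seed, clusters = clusters,
                      prop_pre = as.list(prop_pre),
                      prop_post = as.list(prop_post),
                      eroded_cluster = eroded_cluster,
                      program_lfc = program_lfc,
                      programs = lapply(cluster_programs, function(p)
                        list(name = p$name, genes = p$genes,
                             direction = p$direction)))
    )
  })
}

#' Simulate a patient cohort and a treatment experiment with a reversible
#' signature
#'
#' Patient expression (linear scale, log-normal noise) for `n_patients`
#' patients of whom a fraction are recurrent (biochemical-recurrence-like
#' labels, default 49 of 100); the planted signature genes are shifted up by
#' `effect_log2` log2-units in recurrent patients. A treatment experiment
#' (pre/post groups of `n_treatment_per_group` samples) shifts the overlap
#' genes *down* by `effect_log2` post-treatment — the reversible signature a
#' reverse-matching screen should recover.
#'
#' @param n_patients cohort size.
#' @param recurrent_fraction fraction recurrent (default 0.49).
#' @param n_genes total genes (fillers named G0001...).
#' @param signature_genes planted recurrence-associated genes (default: a
#'   10-gene symbol set led by LTB4R, IFITM3, TMEM120B).
#' @param treatment_signature_overlap subset of `signature_genes` reversed by
#'   treatment (default: all of them).
#' @param effect_log2 planted shift in log2 units.
#' @param noise_sd per-sample noise sd in log2 units.
#' @param n_treatment_per_group samples per treatment arm.
#' @param seed RNG seed.
#' @return list with `patient` (`expr` genes x patients, `recurrent` logical
#'   named vector), `treatment` (`pre`, `post` matrices) and `manifest`.
#' @export
simulate_cohort <- function(n_patients = 100, recurrent_fraction = 0.49,
                            n_genes = 1000,
                            signature_genes = c("LTB4R", "IFITM3", "TMEM120B",
                                                "C1S", "LGALS3BP", "MAT2A",
                                                "CXCL2", "FAS", "HES1",
                                                "CD44"),
                            treatment_signature_overlap = signature_genes,
                            effect_log2 = 2, noise_sd = 0.4,
                            n_treatment_per_group = 30, seed = 1L) {
  stopifnot(all(treatment_signature_overlap %in% signature_genes),
            recurrent_fraction > 0, recurrent_fraction < 1,
            n_genes > length(signature_genes))
  genes <- c(signature_genes,
             sprintf("G%04d", seq_len(n_genes - length(signature_genes))))
  n_rec <- round(recurrent_fraction * n_patients)
  withr_seed(seed, {
    base <- stats::rnorm(n_genes, 5, 1)
    names(base) <- genes
    recurrent <- stats::setNames(
      seq_len(n_patients) %in% sample.int(n_patients, n_rec),
      sprintf("pt%03d", seq_len(n_patients)))

    pat_log2 <- matrix(base, n_genes, n_patients) +
      matrix(stats::rnorm(n_genes * n_patients, 0, noise_sd), n_genes)
    dimnames(pat_log2) <- list(genes, names(recurrent))
    pat_log2[signature_genes, recurrent] <-
      pat_log2[signature_genes, recurrent] + effect_log2

    n_t <- n_treatment_per_group
    mk <- function(shift_genes, shift, prefix) {
      m <- matrix(base, n_genes, n_t) +
        matrix(stats::rnorm(n_genes * n_t, 0, noise_sd), n_genes)
      dimnames(m) <- list(genes, sprintf("%s%02d", prefix, seq_len(n_t)))
      if (length(shift_genes)) m[shift_genes, ] <- m[shift_genes, ] + shift
      2^m
    }
    pre <- mk(character(), 0, "pre")
    post <- mk(treatment_signature_overlap, -effect_log2, "post")

    list(
      patient = list(expr = 2^pat_log2, recurrent = recurrent),
      treatment = list(pre = pre, post = post),
      manifest = list(seed = seed, signature_genes = signature_genes,
                      overlap = treatment_signature_overlap,
                      effect_log2 = effect_log2,
                      n_recurrent = n_rec,
                      n_non_recurrent = n_patients - n_rec)
    )
  })
}
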