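#' Classify cell lines as sensitive or resistant to a primary drug
#'
#' The threshold is the empirical `q`-quantile (linear interpolation between
#' order statistics, [stats::quantile()] type 7) of the primary drug's
#' non-missing IC50 values. A line is *resistant* iff its IC50 is strictly
#' greater than the threshold, *sensitive* otherwise; lines without a
#' primary-drug measurement are *unknown*.
#'
#' @param panel a [dose_response_panel()].
#' @param primary_drug_id drug to classify against (e.g. docetaxel).
#' @param q quantile in (0,1); default 0.75 labels roughly the upper quartile
#'   resistant.
#' @return An object of class `resistance_classification`: list with
#'   `primary_drug_id`, `quantile_q`, `threshold_value` (nM) and `labels`
#'   (named character: `"sensitive"`, `"resistant"`, `"unknown"`).
#' @export
classify_resistance <- function(panel, primary_drug_id, q = 0.75) {
  stopifnot(inherits(panel, "dose_response_panel"), q > 0, q < 1)
  if (!primary_drug_id %in% panel$drug_ids) {
    stop("primary drug not in panel: ", primary_drug_id)
  }
  x <- panel$ic50[primary_drug_id, ]
  if (sum(!is.na(x)) < 4L) {
    stop("fewer than 4 evaluable lines for the primary drug; quantile unstable")
  }
  thr <- unname(stats::quantile(x, q, na.rm = TRUE, type = 7))
  labels <- ifelse(is.na(x), "unknown", ifelse(x > thr, "resistant", "sensitive"))
  structure(
    list(primary_drug_id = primary_drug_id, quantile_q = q,
         threshold_value = thr,
         labels = stats::setNames(labels, panel$cell_line_ids)),
    class = "resistance_classification"
  )
}

#' @export
print.resistance_classification <- function(x, ...) {
  tab <- table(factor(x$labels, c("sensitive", "resistant", "unknown")))
  cat(sprintf("<resistance_classification> primary=%s q=%.2f threshold=%.3g nM\n",
              x$primary_drug_id, x$quantile_q, x$threshold_value))
  cat(sprintf("  sensitive=%d resistant=%d unknown=%d\n",
              tab[["sensitive"]], tab[["resistant"]], tab[["unknown"]]))
  invisible(x)
}

#' Kill rule for secondary-drug evaluation
#'
#' Defines when candidate drug k "kills" a resistant line i. In
#' `per_drug_quantile` mode (default) the line is killed iff its IC50 for k is
#' at or below the `q_kill` quantile of drug k's IC50 distribution across
#' *all* lines — i.e. the line sits in the more-sensitive part of that drug's
#' own potency range, which avoids cross-drug potency-scale artifacts. In
#' `absolute` mode a fixed concentration cutoff (nM) is used instead.
#'
#' @param mode `"per_drug_quantile"` or `"absolute"`.
#' @param q_kill kill quantile in (0,1); only in `per_drug_quantile` mode.
#' @param cutoff_nM absolute cutoff (nM); only in `absolute` mode.
#' @return A `kill_rule` object.
#' @export
kill_rule <- function(mode = c("per_drug_quantile", "absolute"),
                      q_kill = 0.5, cutoff_nM = NULL) {
  mode <- match.arg(mode)
  if (mode == "per_drug_quantile") {
    stopifnot(is.numeric(q_kill), q_kill > 0, q_kill < 1)
    out <- list(mode = mode, q_kill = q_kill)
  } else {
    stopifnot(is.numeric(cutoff_nM), cutoff_nM > 0)
    out <- list(mode = mode, cutoff_nM = cutoff_nM)
  }
  structure(out, class = "kill_rule")
}

#' Rank candidate secondary drugs by resistant-line kill count
#'
#' For each candidate drug k (the primary drug is excluded) the kill count is
#' the number of resistant lines with a present IC50 at or below the kill
#' threshold of the [kill_rule()]. Drugs are ordered by kill count
#' (descending); ties are broken by lower mean log10 IC50 over the evaluable
#' resistant lines, then lexicographically by drug id so the ranking is
#' deterministic.
#'
#' Lines with a missing IC50 for drug k are excluded from both the kill count
#' and `n_evaluable_resistant`; drugs measured in fewer than half of the
#' resistant lines are flagged (`low_coverage`), not dropped.
#'
#' @param panel a [dose_response_panel()].
#' @param classification a [classify_resistance()] result.
#' @param rule a [kill_rule()].
#' @param drug_annotations optional `data.frame` with `drug_id`, `target`,
#'   `target_pathway`, joined onto the output.
#' @return `data.frame` of class `secdrug_ranking`, sorted, with columns
#'   `rank`, `drug_id`, `kill_count`, `n_evaluable_resistant`,
#'   `mean_log_ic50_resistant` (log10 nM), `low_coverage`, and (if annotated)
#'   `target`, `target_pathway`.
#' @export
rank_secdrugs <- function(panel, classification, rule = kill_rule(),
                          drug_annotations = NULL) {
  stopifnot(inherits(panel, "dose_response_panel"),
            inherits(classification, "resistance_classification"),
            inherits(rule, "kill_rule"))
  res_ids <- names(classification$labels)[classification$labels == "resistant"]
  if (length(res_ids) == 0L) {
    stop("zero resistant lines; lower the classification quantile q")
  }
  candidates <- setdiff(panel$drug_ids, classification$primary_drug_id)
  if (length(candidates) == 0L) stop("no candidate drug besides the primary")

  rows <- lapply(candidates, function(k) {
    all_vals <- panel$ic50[k, ]
    thr <- if (rule$mode == "per_drug_quantile") {
      if (sum(!is.na(all_vals)) == 0L) NA_real_
      else unname(stats::quantile(all_vals, rule$q_kill, na.rm = TRUE, type = 7))
    } else rule$cutoff_nM
    rv <- all_vals[res_ids]
    ev <- !is.na(rv)
    data.frame(
      drug_id = k,
      kill_count = if (is.na(thr)) 0L else sum(rv[ev] <= thr),
      n_evaluable_resistant = sum(ev),
      mean_log_ic50_resistant = if (any(ev)) mean(log10(rv[ev])) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$low_coverage <- out$n_evaluable_resistant < 0.5 * length(res_ids)
  ord <- order(-out$kill_count, out$mean_log_ic50_resistant, out$drug_id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(drug_annotations)) {
    out <- merge(out, drug_annotations[, c("drug_id", "target", "target_pathway")],
                 by = "drug_id", all.x = TRUE, sort = FALSE)
    out <- out[order(out$rank), , drop = FALSE]
  }
  rownames(out) <- NULL
  cols <- c("rank", "drug_id", "kill_count", "n_evaluable_resistant",
            "mean_log_ic50_resistant", "low_coverage")
  out <- out[, c(cols, setdiff(names(out), cols)), drop = FALSE]
  class(out) <- c("secdrug_ranking", "data.frame")
  attr(out, "n_resistant") <- length(res_ids)
  attr(out, "kill_rule") <- rule
  out
}
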