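#' Wilcoxon rank-sum p-values per matrix row
#'
#' Exact p (via [stats::wilcox.test()]) when both groups have <= 25 samples
#' and the row is tie-free; otherwise the normal approximation with tie
#' correction and continuity correction, vectorised across rows. The two
#' paths agree with `wilcox.test()` row by row.
#'
#' @param A,B numeric matrices, genes x samples, same rownames.
#' @return numeric vector of two-sided p-values per row.
#' @export
row_wilcoxon <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  nA <- ncol(A); nB <- ncol(B); N <- nA + nB
  X <- cbind(A, B)
  p <- numeric(nrow(A))
  exact_ok <- nA <= 25 && nB <= 25
  for (g in seq_len(nrow(A))) {
    xs <- X[g, ]
    if (length(unique(xs)) == 1L) { p[g] <- 1; next }
    ties <- anyDuplicated(xs) > 0
    if (exact_ok && !ties) {
      p[g] <- stats::wilcox.test(X[g, seq_len(nA)], X[g, nA + seq_len(nB)],
                                 exact = TRUE)$p.value
    } else {
      r <- rank(xs)
      U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
      tie_tab <- table(xs)
      sigma2 <- nA * nB / 12 *
        ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
      z <- U - nA * nB / 2
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p[g] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  p
}

#' Differential expression by Wilcoxon rank-sum with a fold-change gate
#'
#' Per gene: two-sided Wilcoxon rank-sum p between the groups and
#' `log2FC = log2((mean_A + c) / (mean_B + c))` with pseudocount `c`.
#' A gene is *significant* iff raw `p < p_threshold` and
#' `|log2FC| >= fc_threshold` — the raw-p gate is the convention of simple
#' two-group screens; the Benjamini-Hochberg adjusted p is reported alongside
#' for users who want it. Constant genes get p = 1 (and log2FC 0 when means
#' are equal).
#'
#' @param expr_A,expr_B normalized expression matrices, genes x samples, with
#'   identical rownames; >= 3 samples each (>= 20 cells for single-cell use).
#' @param p_threshold raw-p gate (default 0.05).
#' @param fc_threshold `|log2FC|` gate (default 1; a "mean fold-change > |1|"
#'   criterion is read on the log2 scale, since a linear fold-change > 1 is
#'   vacuous).
#' @param pseudocount stabilizer `c` for the fold change (default 1).
#' @return `data.frame` of class `de_result`: `gene`, `mean_A`, `mean_B`,
#'   `log2FC`, `p`, `p_adj`, `significant`, `direction` (`"up"` = higher in
#'   A).
#' @export
differential_expression <- function(expr_A, expr_B, p_threshold = 0.05,
                                    fc_threshold = 1, pseudocount = 1) {
  expr_A <- as.matrix(expr_A); expr_B <- as.matrix(expr_B)
  stopifnot(identical(rownames(expr_A), rownames(expr_B)),
            !is.null(rownames(expr_A)),
            ncol(expr_A) >= 3, ncol(expr_B) >= 3)
  mean_A <- rowMeans(expr_A)
  mean_B <- rowMeans(expr_B)
  log2FC <- log2((mean_A + pseudocount) / (mean_B + pseudocount))
  p <- row_wilcoxon(expr_A, expr_B)
  out <- data.frame(
    gene = rownames(expr_A), mean_A = mean_A, mean_B = mean_B,
    log2FC = log2FC, p = p, p_adj = stats::p.adjust(p, "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$significant <- out$p < p_threshold & abs(out$log2FC) >= fc_threshold
  out$direction <- ifelse(out$log2FC >= 0, "up", "down")
  attr(out, "thresholds") <- list(p = p_threshold, fc = fc_threshold,
                                  pseudocount = pseudocount)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Reverse-match a treatment signature against a patient signature
#'
#' Finds genes significant in both differential-expression results with
#' *opposite* directions — the treatment moves them against the disease
#' signature. Genes up in patients (e.g. in the recurrent group) and down
#' after treatment are the headline direction and are reported first.
#'
#' @param patient_de,treatment_de [differential_expression()] results (e.g.
#'   recurrent-vs-non-recurrent patients; post-vs-pre treatment).
#' @return list of class `reverse_match`: `matches` (`data.frame`: `gene`,
#'   `patient_direction`, `treatment_direction`, `patient_log2FC`,
#'   `treatment_log2FC`, sorted headline-direction first, then by
#'   `|patient_log2FC|` descending) and `summary` (counts per direction pair).
#' @export
reverse_match <- function(patient_de, treatment_de) {
  stopifnot(inherits(patient_de, "de_result"),
            inherits(treatment_de, "de_result"))
  shared <- intersect(patient_de$gene, treatment_de$gene)
  if (length(shared) == 0L) stop("no shared genes between the two results")
  pa <- patient_de[match(shared, patient_de$gene), ]
  tr <- treatment_de[match(shared, treatment_de$gene), ]
  hit <- pa$significant & tr$significant & pa$direction != tr$direction
  matches <- data.frame(
    gene = shared[hit],
    patient_direction = pa$direction[hit],
    treatment_direction = tr$direction[hit],
    patient_log2FC = pa$log2FC[hit],
    treatment_log2FC = tr$log2FC[hit],
    stringsAsFactors = FALSE
  )
  matches <- matches[order(matches$patient_direction != "up",
                           -abs(matches$patient_log2FC)), , drop = FALSE]
  rownames(matches) <- NULL
  summary <- data.frame(
    patient_direction = c("up", "down"),
    treatment_direction = c("down", "up"),
    n = c(sum(matches$patient_direction == "up"),
          sum(matches$patient_direction == "down"))
  )
  structure(list(matches = matches, summary = summary,
                 n_shared = length(shared)),
            class = "reverse_match")
}

#' @export
print.reverse_match <- function(x, ...) {
  cat(sprintf("<reverse_match> %d reversed gene(s) of %d shared\n",
              nrow(x$matches), x$n_shared))
  if (nrow(x$matches)) {
    utils::head(x$matches, 10) |> print()
  }
  invisible(x)
}
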