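# Independent oracles and tiny fixture builders.
# These deliberately re-derive results by explicit loops / enumeration and
# never call the implementation paths they check.

# small panel from a matrix with default ids
tiny_panel <- function(m, drugs = paste0("d", seq_len(nrow(m))),
                       lines = paste0("L", seq_len(ncol(m))), ann = NULL) {
  dimnames(m) <- list(drugs, lines)
  dose_response_panel(m, annotations = ann)
}

# brute-force secDrug ranking: explicit double loop over drugs x resistant
# lines, sort by the stated key. Independent of rank_secdrugs internals.
brute_force_ranking <- function(ic50, primary, q, q_kill) {
  prim <- ic50[primary, ]
  thr <- as.numeric(stats::quantile(prim, q, na.rm = TRUE, type = 7))
  resistant <- colnames(ic50)[!is.na(prim) & prim > thr]
  cands <- setdiff(rownames(ic50), primary)
  rows <- NULL
  for (k in cands) {
    kill_thr <- as.numeric(stats::quantile(ic50[k, ], q_kill, na.rm = TRUE,
                                           type = 7))
    kills <- 0L; n_ev <- 0L; logs <- c()
    for (i in resistant) {
      v <- ic50[k, i]
      if (!is.na(v)) {
        n_ev <- n_ev + 1L
        logs <- c(logs, log10(v))
        if (v <= kill_thr) kills <- kills + 1L
      }
    }
    rows <- rbind(rows, data.frame(
      drug_id = k, kill_count = kills, n_evaluable_resistant = n_ev,
      mean_log_ic50_resistant = if (n_ev) mean(logs) else NA_real_,
      stringsAsFactors = FALSE))
  }
  rows <- rows[order(-rows$kill_count, rows$mean_log_ic50_resistant,
                     rows$drug_id, method = "radix"), ]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

# random small panel on a fixed IC50 grid (values drawn from a discrete grid
# so ties between lines/drugs occur and exercise the tie-breaks)
random_grid_panel <- function(K, n, missing_rate = 0.1) {
  grid <- 10^seq(0, 3, by = 0.25)
  m <- matrix(sample(grid, K * n, replace = TRUE), K, n)
  if (missing_rate > 0) m[runif(K * n) < missing_rate] <- NA
  # primary drug needs >= 4 values
  while (sum(!is.na(m[1, ])) < 4) m[1, ] <- sample(grid, n, replace = TRUE)
  tiny_panel(m)
}

# 4PL survival used to build oracle curves (kept separate from the package's
# internal model function on purpose)
oracle_4pl <- function(D, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (D / ic50)^hill)
}

# dense grid-search RSS oracle for the 4PL fit
grid_search_4pl_rss <- function(curve) {
  pts <- curve[curve$concentration_nM > 0, ]
  D <- pts$concentration_nM; y <- pts$percent_survival
  best <- Inf
  for (b in seq(min(y) - 5, min(y) + 10, length.out = 8))
    for (t in seq(max(y) - 10, max(y) + 5, length.out = 8))
      for (ic in 10^seq(log10(min(D)), log10(max(D)), length.out = 25))
        for (h in seq(0.4, 3, length.out = 14)) {
          rss <- sum((y - oracle_4pl(D, b, t, ic, h))^2)
          if (rss < best) best <- rss
        }
  best
}
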