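test_that("resistance classification uses the interpolated quantile with strict >", {
  p <- tiny_panel(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4, byrow = TRUE))
  cl <- classify_resistance(p, "d1", q = 0.5)
  expect_equal(cl$threshold_value, 2.5)
  expect_equal(unname(cl$labels), c("sensitive", "sensitive", "resistant",
                                    "resistant"))

  # degenerate distribution: all equal -> nobody strictly above the threshold
  pe <- tiny_panel(matrix(c(rep(5, 4), 1:4), 2, 4, byrow = TRUE))
  cle <- classify_resistance(pe, "d1", q = 0.25)
  expect_equal(sum(cle$labels == "resistant"), 0)

  # missing primary-drug values are labelled unknown
  m <- matrix(c(1, 2, 3, 4, NA, 1, 1, 1, 1, 1), 2, 5, byrow = TRUE)
  clm <- classify_resistance(tiny_panel(m), "d1", q = 0.5)
  expect_equal(unname(clm$labels["L5"]), "unknown")

  expect_error(classify_resistance(tiny_panel(matrix(1:6, 2, 3)), "d1", 0.5),
               "fewer than 4")
  expect_error(classify_resistance(p, "d1", q = 1), "q < 1")
})

test_that("a planted high-IC50 subgroup is recovered by the quantile rule", {
  set.seed(42)
  n <- 100
  planted <- sample(n, 20)
  logv <- rnorm(n, 1.5, 0.2)
  logv[planted] <- logv[planted] + 1.5
  m <- rbind(10^logv, 10^rnorm(n, 1.5, 0.2))
  p <- tiny_panel(m, lines = sprintf("L%03d", 1:n))
  cl <- classify_resistance(p, "d1", q = 0.8)
  # brute-force check: resistant = strictly above the sorted 80% point
  thr <- as.numeric(quantile(10^logv, 0.8, type = 7))
  expect_identical(names(which(cl$labels == "resistant")),
                   sprintf("L%03d", which(10^logv > thr)))
  expect_gte(sum(cl$labels[planted] == "resistant"), 18)
})

test_that("ranking follows kill count, then mean log IC50, then drug id", {
  # drug A kills all 3 resistant lines, B kills 1 -> strict dominance
  m <- rbind(
    primary = c(1, 1, 1, 100, 100, 100),
    A = c(50, 50, 50, 1, 2, 3),
    B = c(1, 2, 3, 1, 50, 60)
  )
  p <- tiny_panel(m, drugs = rownames(m))
  cl <- classify_resistance(p, "primary", q = 0.5)
  rk <- rank_secdrugs(p, cl)
  expect_equal(rk$drug_id, c("A", "B"))
  expect_equal(rk$kill_count, c(3L, 1L))
  expect_equal(rk$rank, 1:2)

  # equal kill counts -> lower mean log10 IC50 over resistant lines wins
  m2 <- rbind(
    primary = c(1, 1, 1, 100, 100),
    A = c(100, 100, 100, 1, 1),
    B = c(100, 100, 100, 10, 10)
  )
  p2 <- tiny_panel(m2, drugs = rownames(m2))
  cl2 <- classify_resistance(p2, "primary", q = 0.5)
  rk2 <- rank_secdrugs(p2, cl2)
  expect_equal(rk2$kill_count, c(2L, 2L))
  expect_equal(rk2$drug_id, c("A", "B"))
  expect_lt(rk2$mean_log_ic50_resistant[1], rk2$mean_log_ic50_resistant[2])
})

test_that("ranking equals the brute-force enumeration oracle on small panels", {
  set.seed(7)
  for (i in 1:60) {
    K <- sample(2:6, 1); n <- sample(4:8, 1)
    p <- random_grid_panel(K, n)
    cl <- classify_resistance(p, "d1", q = 0.5)
    if (sum(cl$labels == "resistant") == 0) next
    got <- rank_secdrugs(p, cl, kill_rule(q_kill = 0.5))
    want <- brute_force_ranking(p$ic50, "d1", 0.5, 0.5)
    expect_equal(got$drug_id, want$drug_id)
    expect_equal(got$kill_count, want$kill_count)
    expect_equal(got$mean_log_ic50_resistant, want$mean_log_ic50_resistant)
  }
})

test_that("ranking is invariant to row/column permutations of the panel", {
  set.seed(3)
  sim <- simulate_pgx_panel(n_lines = 40, K_drugs = 10, seed = 3)
  p <- sim$panel
  cl <- classify_resistance(p, "primary")
  rk <- rank_secdrugs(p, cl)

  perm <- dose_response_panel(
    p$ic50[sample(nrow(p$ic50)), sample(ncol(p$ic50))])
  clp <- classify_resistance(perm, "primary")
  rkp <- rank_secdrugs(perm, clp)
  expect_identical(rk$drug_id, rkp$drug_id)
  expect_identical(rk$kill_count, rkp$kill_count)
})

test_that("a strict superset kill set always ranks higher", {
  set.seed(9)
  for (i in 1:30) {
    p <- random_grid_panel(sample(3:6, 1), sample(5:8, 1))
    cl <- classify_resistance(p, "d1", q = 0.5)
    res <- names(cl$labels)[cl$labels == "resistant"]
    if (!length(res)) next
    rk <- rank_secdrugs(p, cl)
    kill_set <- function(k) {
      thr <- quantile(p$ic50[k, ], 0.5, na.rm = TRUE, type = 7)
      v <- p$ic50[k, res]
      res[!is.na(v) & v <= thr]
    }
    sets <- lapply(rk$drug_id, kill_set)
    names(sets) <- rk$drug_id
    for (a in rk$drug_id) for (b in rk$drug_id) {
      if (a != b && all(sets[[b]] %in% sets[[a]]) &&
          length(sets[[a]]) > length(sets[[b]])) {
        expect_lt(rk$rank[rk$drug_id == a], rk$rank[rk$drug_id == b])
      }
    }
  }
})

test_that("identical inputs give identical rankings and annotations join", {
  sim <- simulate_pgx_panel(seed = 21)
  cl <- classify_resistance(sim$panel, "primary")
  r1 <- rank_secdrugs(sim$panel, cl, drug_annotations = sim$manifest$drug_annotations)
  r2 <- rank_secdrugs(sim$panel, cl, drug_annotations = sim$manifest$drug_annotations)
  expect_identical(r1, r2)
  planted_row <- r1[r1$drug_id == sim$manifest$planted_secdrugs[1], ]
  expect_equal(planted_row$target, "NAMPT")
  expect_equal(planted_row$target_pathway, "NAD+ salvage pathway")
})

test_that("errors guide the caller on degenerate classifications", {
  m <- rbind(primary = c(5, 5, 5, 5), A = 1:4)
  p <- tiny_panel(m, drugs = rownames(m))
  cl <- classify_resistance(p, "primary", q = 0.5)
  expect_error(rank_secdrugs(p, cl), "lower the classification quantile")

  one <- tiny_panel(matrix(1:4, 1, 4), drugs = "primary")
  clo <- classify_resistance(one, "primary", q = 0.5)
  expect_error(rank_secdrugs(one, clo), "no candidate drug")
})
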