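small_sim <- function(seed = 1, erode = "psat1_high") {
  simulate_sc_counts(
    n_cells_per_cluster = c(bulk = 120, emt = 60, stemness = 60,
                            psat1_high = 80),
    eroded_cluster = erode, n_filler_genes = 80, seed = seed)
}

test_that("count normalization matches the CP10K log1p definition", {
  m <- matrix(c(100, 9900, 0,
                10, 10, 20,
                5, 0, 5), 3, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("c1", "c2", "c3")))
  x <- normalize_counts(cell_counts(m, cluster = "a"))
  # cell c1 has depth 115: value = log1p(count / 115 * 1e4)
  expect_equal(x$lognorm["g1", "c1"], log1p(100 / 115 * 1e4))
  # a cell with total depth exactly 10,000 keeps log(1 + count)
  m2 <- matrix(c(100, 9900), 2, 1,
               dimnames = list(c("g1", "g2"), "c1"))
  x2 <- normalize_counts(cell_counts(m2, cluster = "a"))
  expect_equal(x2$lognorm["g1", "c1"], log(1 + 100))

  # depth invariance: doubling all counts of a cell changes nothing
  x3 <- normalize_counts(cell_counts(m * 2, cluster = "a"))
  expect_equal(as.matrix(x3$lognorm), as.matrix(x$lognorm))

  # zero-depth cells dropped with a warning; all-zero is an error
  mz <- cbind(m, c4 = c(0, 0, 0))
  expect_warning(xz <- normalize_counts(cell_counts(mz, cluster = "a")),
                 "zero-depth")
  expect_equal(ncol(xz$counts), 3)
  expect_error(normalize_counts(cell_counts(m * 0, cluster = "a")),
               "all-zero")
})

test_that("program scoring saturates, discriminates, and respects direction", {
  s <- small_sim(seed = 11)
  pre <- normalize_counts(s$pre)

  # saturation: single up-gene present in every cell of a cluster
  m <- matrix(c(5, 3, 2, 8), 1, 4,
              dimnames = list("NAMPT", paste0("c", 1:4)))
  xx <- normalize_counts(cell_counts(rbind(m, OTHER = c(1, 1, 1, 1)),
                                     cluster = "a"))
  scr <- score_program(xx, gene_program("nampt", "NAMPT"))
  expect_equal(scr$fraction_positive, 1)

  # the planted NAD-salvage cluster has the maximal mean score
  nad <- score_program(pre, default_programs()$nad_salvage)
  expect_equal(nad$cluster[which.max(nad$mean_score)], "psat1_high")

  # the planted mesenchymal cluster tops the EMT program (VIM up, CDH1 down)
  emt <- score_program(pre, default_programs()$emt)
  expect_equal(emt$cluster[which.max(emt$mean_score)], "emt")

  # gene order and cell order do not matter
  perm <- cell_counts(s$pre$counts[sample(nrow(s$pre$counts)),
                                   sample(ncol(s$pre$counts))],
                      cluster = "tmp")
  perm$cells <- s$pre$cells[match(colnames(perm$counts),
                                  s$pre$cells$cell_id), ]
  nad2 <- score_program(normalize_counts(perm), default_programs()$nad_salvage)
  expect_equal(nad2, nad, ignore_attr = TRUE)

  # absent genes: dropped with warning, all-absent is an error
  expect_warning(score_program(pre, gene_program("mix", c("NAMPT", "NOPE"))),
                 "absent")
  expect_error(score_program(pre, gene_program("none", "NOPE")),
               "no program gene")
})

test_that("fraction_positive is monotone in a cell's program counts", {
  set.seed(5)
  m <- matrix(rpois(60, 0.5), 3, 20,
              dimnames = list(c("NAMPT", "NAPRT", "PSAT1"), sprintf("c%02d", 1:20)))
  x <- normalize_counts(cell_counts(rbind(m, FILLER = 5), cluster = "a"))
  base <- score_program(x, default_programs()$nad_salvage)$fraction_positive
  m2 <- m; m2[, 1:10] <- m2[, 1:10] + 2  # raise program counts in half the cells
  x2 <- normalize_counts(cell_counts(rbind(m2, FILLER = 5), cluster = "a"))
  bumped <- score_program(x2, default_programs()$nad_salvage)$fraction_positive
  expect_gte(bumped, base)
})

test_that("double-hit fuses rank and coverage and honours edge cases", {
  sim <- simulate_pgx_panel(seed = 13)
  cl <- classify_resistance(sim$panel, "primary")
  rk <- rank_secdrugs(sim$panel, cl)
  K <- nrow(rk)
  planted <- sim$manifest$planted_secdrugs[1]
  expect_equal(rk$drug_id[1], planted)

  s <- small_sim(seed = 13)
  pre <- normalize_counts(s$pre)
  nad_screen <- score_program(pre, default_programs()$nad_salvage)

  # competitor drugs: a program of filler genes (low coverage everywhere)
  filler_screen <- score_program(pre, gene_program("filler",
    c("G0001", "G0002", "G0003")))
  screens <- c(
    stats::setNames(list(nad_screen), planted),
    stats::setNames(rep(list(filler_screen), 2), rk$drug_id[2:3])
  )
  dh <- double_hit(rk, screens, flagged_clusters = c("psat1_high", "stemness"))
  expect_equal(dh$drug_id[1], planted)
  expect_equal(dh$secdrug_rank_score[1], 1)
  expect_true(all(dh$double_hit >= 0 & dh$double_hit <= 1))

  # rank-1 with coverage 1 -> exactly 1; coverage 0 -> exactly 0
  perfect <- nad_screen; perfect$fraction_positive <- 1
  none <- nad_screen; none$fraction_positive <- 0
  expect_equal(double_hit(rk, stats::setNames(list(perfect), planted),
                          "psat1_high")$double_hit, 1)
  expect_equal(double_hit(rk, stats::setNames(list(none), planted),
                          "psat1_high")$double_hit, 0)

  expect_warning(double_hit(rk, stats::setNames(list(nad_screen), planted),
                            character()), "all clusters")
})

test_that("cluster erosion is flagged only where composition truly collapses", {
  # identical compositions: nothing flagged
  lab <- rep(c("a", "b", "c"), c(500, 300, 200))
  null_res <- detect_cluster_erosion(lab, lab)
  expect_false(any(null_res$eroded))

  # hand-planted erosion 20% -> 0%: Fisher oracle by hypergeometric sum
  pre <- rep(c("a", "b"), c(400, 100))
  post <- rep(c("a", "b"), c(500, 0))
  res <- detect_cluster_erosion(pre, post)
  expect_true(res$eroded[res$cluster == "b"])
  a <- 100; n_pre <- 500; b <- 0; n_post <- 500
  p_oracle <- fisher.test(matrix(c(a, n_pre - a, b, n_post - b), 2))$p.value
  expect_equal(res$p[res$cluster == "b"], p_oracle)

  # generator-planted erosion: the eroded cluster and only it is flagged
  s <- small_sim(seed = 23)
  res2 <- detect_cluster_erosion(s$pre, s$post)
  expect_identical(res2$cluster[res2$eroded], "psat1_high")
})

test_that("label transfer puts post cells into the pre label space", {
  s <- small_sim(seed = 31)
  post_unlabelled <- s$post
  truth <- post_unlabelled$cells$cluster
  post_unlabelled$cells$cluster <- "unknown"
  transferred <- transfer_labels(s$pre, post_unlabelled)
  expect_gt(mean(transferred$cells$cluster == truth), 0.9)
})

test_that("MTX round-trip preserves counts and metadata", {
  s <- simulate_sc_counts(n_cells_per_cluster = c(a = 20, b = 20),
                          cluster_programs = list(), eroded_cluster = NULL,
                          n_filler_genes = 30, seed = 2)
  d <- withr::local_tempdir()
  write_cell_counts(s$pre, d)
  back <- read_cell_counts(d)
  expect_equal(as.matrix(back$counts), as.matrix(s$pre$counts))
  expect_identical(back$cells$cluster, s$pre$cells$cluster)
  expect_identical(back$cells$condition, s$pre$cells$condition)
})
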