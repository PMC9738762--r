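#' Cell-by-gene count container with cluster/condition metadata
#'
#' Light container for droplet-style single-cell counts. Genes are rows and
#' cells columns (sparse [Matrix::dgCMatrix-class] allowed); clustering is an
#' *input* here — labels come from upstream (graph-based or otherwise) or from
#' the bundled deterministic k-means baseline.
#'
#' @param counts non-negative integer matrix or sparse Matrix, genes x cells,
#'   with unique rownames (genes) and colnames (cell barcodes).
#' @param cluster per-cell cluster labels (non-empty, length = ncol(counts)).
#' @param condition per-cell condition, `"pre"` or `"post"` (optional,
#'   defaults to `"pre"`).
#' @param sample_id per-cell sample identifier (optional).
#' @return object of class `cell_counts`: list with `counts` and `cells`
#'   (`data.frame`: `cell_id`, `cluster`, `condition`, `sample_id`), plus a
#'   `lognorm` slot filled by [normalize_counts()].
#' @export
cell_counts <- function(counts, cluster, condition = "pre", sample_id = "s1") {
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts) * 1.0, sparse = TRUE)
  }
  counts <- methods::as(counts, "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts needs gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (length(counts@x) && min(counts@x) < 0) stop("counts must be non-negative")
  n <- ncol(counts)
  cluster <- as.character(rep_len(cluster, n))
  if (any(is.na(cluster) | cluster == "")) stop("all cells need a cluster label")
  condition <- as.character(rep_len(condition, n))
  stopifnot(all(condition %in% c("pre", "post")))
  cells <- data.frame(cell_id = colnames(counts), cluster = cluster,
                      condition = condition,
                      sample_id = rep_len(sample_id, n),
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, cells = cells, lognorm = NULL),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d genes x %d cells, %d clusters (%s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cells$cluster)),
              paste(unique(x$cells$condition), collapse = "/")))
  invisible(x)
}

#' Depth-normalize and log-transform counts
#'
#' Scales each cell to a library size of 10,000 and applies `log(1 + x)`:
#' the standard counts-per-10k log normalization, which makes a cell's
#' profile invariant to doubling its sequencing depth. Zero-depth cells are
#' dropped with a warning.
#'
#' @param x a [cell_counts()] object.
#' @param scale_to target library size (default 1e4).
#' @return `x` with the `lognorm` slot filled (sparse genes x cells matrix).
#' @export
normalize_counts <- function(x, scale_to = 1e4) {
  stopifnot(inherits(x, "cell_counts"))
  depth <- Matrix::colSums(x$counts)
  if (all(depth == 0)) stop("all-zero count matrix")
  if (any(depth == 0)) {
    warning(sprintf("dropping %d zero-depth cell(s)", sum(depth == 0)))
    keep <- depth > 0
    x$counts <- x$counts[, keep, drop = FALSE]
    x$cells <- x$cells[keep, , drop = FALSE]
    depth <- depth[keep]
  }
  cpk <- x$counts %*% Matrix::Diagonal(x = scale_to / depth)
  colnames(cpk) <- colnames(x$counts)
  x$lognorm <- log1p(cpk)
  x
}

#' Marker-gene program with per-gene directions
#'
#' A named gene set with an expected direction per gene, e.g. the EMT program
#' (VIM up, CDH1 down) or a drug's target-pathway program (NAMPT, NAPRT,
#' PSAT1 up for a NAD+ salvage inhibitor).
#'
#' @param name program name.
#' @param genes gene identifiers (no duplicates).
#' @param direction `"up"` or `"down"` per gene (recycled).
#' @return object of class `gene_program`.
#' @export
gene_program <- function(name, genes, direction = "up") {
  stopifnot(length(genes) >= 1, !anyDuplicated(genes))
  direction <- rep_len(direction, length(genes))
  stopifnot(all(direction %in% c("up", "down")))
  structure(list(name = name, genes = as.character(genes),
                 direction = direction),
            class = "gene_program")
}

#' Bundled marker programs
#'
#' EMT (mesenchymal markers up, E-cadherin down), stemness, and the NAD+
#' salvage pathway program targeted by NAMPT inhibitors such as FK866.
#'
#' @return named list of [gene_program()] objects.
#' @export
default_programs <- function() {
  list(
    emt = gene_program("emt",
      c("VIM", "CDH2", "FN1", "S100A4", "SNAI1", "SNAI2", "CDH11", "TWIST1",
        "ZEB1", "CDH1"),
      c(rep("up", 9), "down")),
    stemness = gene_program("stemness", c("PLAU", "PLAUR", "CD44", "HES1")),
    nad_salvage = gene_program("nad_salvage", c("NAMPT", "NAPRT", "PSAT1"))
  )
}

#' Score a marker program per cluster
#'
#' Per-cell score: mean over the program genes present in the matrix of the
#' signed log-normalized expression (down-direction genes negated). A cell is
#' *positive* for the program iff more than `positivity` of its up-direction
#' genes have a nonzero count — a dropout-robust reading of "high expression"
#' of the program. Results are aggregated per cluster.
#'
#' @param x a [normalize_counts()]-ed `cell_counts`.
#' @param program a [gene_program()]; absent genes are dropped with a
#'   warning, all-absent is an error.
#' @param positivity fraction threshold for the positivity rule (default 0.5).
#' @return `data.frame` of class `subclone_screen`: `cluster`, `mean_score`,
#'   `fraction_positive`, `n_cells`; attribute `program`.
#' @export
score_program <- function(x, program, positivity = 0.5) {
  stopifnot(inherits(x, "cell_counts"), inherits(program, "gene_program"))
  if (is.null(x$lognorm)) x <- normalize_counts(x)
  present <- program$genes %in% rownames(x$lognorm)
  if (!any(present)) stop("no program gene present in the matrix: ",
                          program$name)
  if (any(!present)) {
    warning(sprintf("program %s: %d gene(s) absent, dropped (%s)",
                    program$name, sum(!present),
                    paste(program$genes[!present], collapse = ", ")))
  }
  genes <- program$genes[present]
  dirs <- program$direction[present]
  sign_vec <- ifelse(dirs == "up", 1, -1)
  expr <- x$lognorm[genes, , drop = FALSE]
  cell_score <- as.numeric(Matrix::crossprod(expr, sign_vec)) / length(genes)

  up_genes <- genes[dirs == "up"]
  if (length(up_genes)) {
    nonzero <- x$counts[up_genes, , drop = FALSE] > 0
    frac_up <- Matrix::colSums(nonzero) / length(up_genes)
    positive <- frac_up > positivity
  } else {
    positive <- rep(NA, ncol(x$counts))
  }

  cl <- x$cells$cluster
  out <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sel <- cl == k
    data.frame(cluster = k, mean_score = mean(cell_score[sel]),
               fraction_positive = mean(positive[sel]),
               n_cells = sum(sel), stringsAsFactors = FALSE)
  }))
  attr(out, "program") <- program$name
  class(out) <- c("subclone_screen", "data.frame")
  out
}

#' Combine the secDrug ranking with single-cell target-pathway coverage
#'
#' The double-hit score fuses the pharmacogenomic evidence (the drug kills
#' resistant lines) with single-cell evidence (its target pathway is expressed
#' in the subclones of concern): `double_hit = secdrug_rank_score *
#' target_coverage`, where `secdrug_rank_score = 1 - (rank - 1)/K` maps rank 1
#' of K drugs to 1, and `target_coverage` is the cell-weighted mean
#' `fraction_positive` of the drug's target-pathway program over the flagged
#' clusters (e.g. the resistant/stem-like subclones).
#'
#' @param ranking a [rank_secdrugs()] result.
#' @param screens named list (by drug_id) of [score_program()] results for
#'   each drug's target-pathway program. Drugs without a screen are skipped.
#' @param flagged_clusters clusters of concern; if empty, coverage is computed
#'   over all clusters with a warning.
#' @return `data.frame` sorted by `double_hit` descending: `drug_id`, `rank`,
#'   `secdrug_rank_score`, `target_coverage`, `double_hit`.
#' @export
double_hit <- function(ranking, screens, flagged_clusters = character()) {
  stopifnot(inherits(ranking, "secdrug_ranking"), is.list(screens))
  K <- nrow(ranking)
  drugs <- intersect(ranking$drug_id, names(screens))
  if (length(drugs) == 0L) stop("no ranked drug has a target-pathway screen")
  rows <- lapply(drugs, function(d) {
    scr <- screens[[d]]
    stopifnot(inherits(scr, "subclone_screen"))
    sel <- if (length(flagged_clusters)) scr$cluster %in% flagged_clusters
           else rep(TRUE, nrow(scr))
    if (!any(sel)) stop("no flagged cluster present in screen for drug ", d)
    cov <- sum(scr$fraction_positive[sel] * scr$n_cells[sel]) /
      sum(scr$n_cells[sel])
    rk <- ranking$rank[ranking$drug_id == d]
    data.frame(drug_id = d, rank = rk,
               secdrug_rank_score = 1 - (rk - 1) / K,
               target_coverage = cov,
               double_hit = (1 - (rk - 1) / K) * cov,
               stringsAsFactors = FALSE)
  })
  if (length(flagged_clusters) == 0L) {
    warning("empty flagged cluster set; coverage computed over all clusters")
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$double_hit, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect treatment-induced cluster erosion
#'
#' Tests, per cluster, whether its share of cells shrinks after treatment —
#' the computational proxy for "loss" of a subclone cluster (e.g. a
#' PSAT1-high cluster vanishing after NAMPT-inhibitor exposure). Each cluster
#' gets a two-sided Fisher exact test on the 2x2 table (in-cluster vs out) x
#' (pre vs post); p-values are Benjamini-Hochberg adjusted across clusters.
#' A cluster is flagged *eroded* iff its post proportion is at most half its
#' pre proportion and the adjusted p is below `alpha`.
#'
#' @param pre,post [cell_counts()] objects, or bare per-cell cluster label
#'   vectors, sharing a cluster label space (transfer labels upstream if
#'   needed; see [transfer_labels()]).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param fold maximal post/pre proportion ratio to call erosion (default 0.5).
#' @return `data.frame`: `cluster`, `n_pre`, `n_post`, `prop_pre`,
#'   `prop_post`, `relative_change`, `p`, `p_adj`, `eroded`.
#' @export
detect_cluster_erosion <- function(pre, post, alpha = 0.05, fold = 0.5) {
  lab_pre <- if (inherits(pre, "cell_counts")) pre$cells$cluster
             else as.character(pre)
  lab_post <- if (inherits(post, "cell_counts")) post$cells$cluster
              else as.character(post)
  clusters <- sort(union(unique(lab_pre), unique(lab_post)))
  n_pre <- length(lab_pre); n_post <- length(lab_post)
  rows <- lapply(clusters, function(k) {
    a <- sum(lab_pre == k); b <- sum(lab_post == k)
    p <- stats::fisher.test(matrix(c(a, n_pre - a, b, n_post - b), 2))$p.value
    data.frame(cluster = k, n_pre = a, n_post = b,
               prop_pre = a / n_pre, prop_post = b / n_post,
               relative_change = (b / n_post - a / n_pre) /
                 ifelse(a > 0, a / n_pre, NA_real_),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out$eroded <- out$prop_post <= fold * out$prop_pre & out$p_adj < alpha &
    out$prop_pre > 0
  out
}

#' Deterministic k-means clustering baseline
#'
#' Fixture-grade clustering: k-means (fixed seed) on the top principal
#' components of the log-normalized matrix. This stands in for upstream
#' graph-based clustering when labels are not supplied; it is a baseline, not
#' a replacement for a real clustering pipeline.
#'
#' @param x a `cell_counts` object.
#' @param k number of clusters.
#' @param n_pcs number of principal components (capped by matrix size).
#' @param seed RNG seed for k-means restarts.
#' @return `x` with `cells$cluster` replaced by `"c1"..."ck"`.
#' @export
cluster_baseline <- function(x, k, n_pcs = 50, seed = 1L) {
  stopifnot(inherits(x, "cell_counts"))
  if (is.null(x$lognorm)) x <- normalize_counts(x)
  m <- t(as.matrix(x$lognorm))
  n_pcs <- min(n_pcs, ncol(m) - 1L, nrow(m) - 1L)
  pcs <- stats::prcomp(m, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  km <- withr_seed(seed, stats::kmeans(pcs, centers = k, nstart = 10))
  x$cells$cluster <- paste0("c", km$cluster)
  x
}

#' Transfer cluster labels from a reference by nearest centroid
#'
#' Assigns each query cell to the nearest (Euclidean, log-normalized space)
#' cluster centroid of the reference — the minimal label-transfer step that
#' puts pre- and post-treatment data into a common cluster label space for
#' [detect_cluster_erosion()].
#'
#' @param reference,query `cell_counts` objects over the same genes.
#' @return `query` with `cells$cluster` set to reference labels.
#' @export
transfer_labels <- function(reference, query) {
  stopifnot(inherits(reference, "cell_counts"), inherits(query, "cell_counts"))
  if (is.null(reference$lognorm)) reference <- normalize_counts(reference)
  if (is.null(query$lognorm)) query <- normalize_counts(query)
  genes <- intersect(rownames(reference$lognorm), rownames(query$lognorm))
  stopifnot(length(genes) > 0)
  ref <- as.matrix(reference$lognorm[genes, , drop = FALSE])
  centroids <- sapply(split(seq_len(ncol(ref)), reference$cells$cluster),
                      function(idx) rowMeans(ref[, idx, drop = FALSE]))
  qm <- as.matrix(query$lognorm[genes, , drop = FALSE])
  # squared distance to each centroid via ||q||^2 - 2 q.c + ||c||^2
  d2 <- -2 * crossprod(qm, centroids) +
    matrix(colSums(centroids^2), ncol(qm), ncol(centroids), byrow = TRUE)
  query$cells$cluster <- colnames(centroids)[max.col(-d2, ties.method = "first")]
  query
}

# run expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a sparse count triplet (MatrixMarket + TSV)
#'
#' The standard droplet exchange format: `matrix.mtx`, `features.tsv`
#' (genes), `barcodes.tsv` (cells), plus `cells.tsv` with cluster/condition
#' metadata.
#'
#' @param x a `cell_counts` object.
#' @param dir output / input directory.
#' @return `write_cell_counts`: `dir` invisibly; `read_cell_counts`: a
#'   `cell_counts`.
#' @export
write_cell_counts <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cell_counts
#' @export
read_cell_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.table(file.path(dir, "cells.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  stopifnot(identical(meta$cell_id, colnames(m)))
  cell_counts(m, meta$cluster, meta$condition, meta$sample_id)
}
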