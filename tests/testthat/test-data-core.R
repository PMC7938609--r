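test_that("dense TSV and matrix-market inputs load to identical states", {
  set.seed(3)
  raw <- matrix(rpois(100, 2), 10, 10,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:10)))
  raw[1, 1] <- 0   # explicit zero survives the triplet encoding
  dir <- withr::local_tempdir()
  write.table(data.frame(gene_id = rownames(raw), raw, check.names = FALSE),
              file.path(dir, "m.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(raw, sparse = TRUE), file.path(dir, "m.mtx"))
  writeLines(rownames(raw), file.path(dir, "genes.tsv"))
  writeLines(colnames(raw), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(cell_id = colnames(raw), x = 1:10, y = 10:1),
              file.path(dir, "coords.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  s1 <- read_inputs(file.path(dir, "m.tsv"), file.path(dir, "coords.tsv"),
                    format = "tsv")
  s2 <- read_inputs(file.path(dir, "m.mtx"), file.path(dir, "coords.tsv"),
                    format = "mtx")
  expect_equal(s1$expr$raw, s2$expr$raw)
  expect_equal(s1$cells, s2$cells)
  expect_equal(dim(s1), c(10L, 10L))

  # unmatched ids are rejected
  write.table(data.frame(cell_id = colnames(raw)[1:9], x = 1:9, y = 1:9),
              file.path(dir, "short.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_inputs(file.path(dir, "m.tsv"),
                           file.path(dir, "short.tsv")), "unmatched cell ids")
})

test_that("filtering removes cells first, then genes, per the thresholds", {
  raw <- matrix(c(0, 2, 3,
                  0, 0, 5,
                  1, 1, 0), 3, 3, byrow = TRUE,
                dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  s <- tiny_state(raw)
  f <- filter_dataset(s, detection_threshold = 1,
                      min_detected_genes_per_cell = 2,
                      min_cells_per_gene = 2)
  # c1 has one detected gene and drops; then g2, g3 are detected in < 2 of
  # the surviving cells
  expect_identical(f$genes$gene_id, "g1")
  expect_identical(f$cells$cell_id, c("c2", "c3"))

  # zero thresholds are a no-op
  f0 <- filter_dataset(s, 0, 0, 0)
  expect_equal(f0$expr$raw, raw)

  expect_error(filter_dataset(s, 1, min_detected_genes_per_cell = 4),
               "exceeds the number of genes")
  expect_error(filter_dataset(s, 1, 3, 0), "all cells removed")
})

test_that("normalization matches the closed form and rescaling conventions", {
  raw <- matrix(c(5, 95, 0, 10, 80, 10), 3, 2,
                dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  s <- normalize_default(tiny_state(raw), scale_factor = 10000)
  # count 5 in a 100-count cell at scale 10000: log2(5/100*10000 + 1)
  expect_equal(s$expr$normalized["g1", "c1"], log2(501), tolerance = 1e-12)

  # identity scaling: scale_factor = libsize gives log2(raw + 1)
  raw2 <- matrix(c(3, 1, 2, 6), 2, 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  s2 <- normalize_default(tiny_state(raw2), scale_factor = 4)
  expect_equal(s2$expr$normalized[, "c1"], log2(raw2[, "c1"] + 1))

  # all-zero (constant) gene yields an all-zero scaled row
  raw3 <- rbind(raw2, g3 = c(0, 0))
  s3 <- normalize_default(tiny_state(raw3), rescale = TRUE)
  expect_equal(unname(s3$expr$scaled["g3", ]), c(0, 0))

  # zero-libsize cells are rejected
  raw4 <- cbind(raw2, c3 = c(0, 0))
  expect_error(normalize_default(tiny_state(raw4)), "zero library size")
})

test_that("per-cell and per-gene statistics are correct", {
  raw <- matrix(c(0, 3, 2, 0), 2, 2, byrow = FALSE,
                dimnames = list(c("g1", "g2"), c("c1", "c2")))
  s <- add_statistics(tiny_state(raw))
  expect_equal(s$cells$total_counts, c(3, 2))
  expect_equal(s$cells$n_detected_genes, c(1, 1))
  expect_equal(s$genes$detection_fraction, c(0.5, 0.5))

  # threshold above the maximum kills all detection
  s2 <- add_statistics(tiny_state(raw), detection_threshold = 10)
  expect_equal(s2$genes$detection_fraction, c(0, 0))

  z <- tiny_state(matrix(0, 2, 2, dimnames = list(c("g1", "g2"),
                                                  c("c1", "c2"))))
  z <- add_statistics(z)
  expect_true(all(z$cells$total_counts == 0) &&
                all(z$genes$mean_expression == 0))
})

test_that("covariate adjustment removes fitted variation, preserves means", {
  set.seed(4)
  s <- random_state(20, 60, seed = 4)
  s <- normalize_default(s)
  s <- add_statistics(s)
  before <- s$expr$normalized

  # a gene perfectly proportional to the covariate flattens to its mean
  cov <- s$cells$total_counts
  s$expr$normalized["g001", ] <- 0.01 * cov
  a <- adjust_for_covariates(s, "total_counts")
  expect_equal(unname(a$expr$normalized["g001", ]),
               rep(mean(0.01 * cov), 60), tolerance = 1e-9)

  # a gene orthogonal to the centered covariate is unchanged
  cc <- cov - mean(cov)
  v <- rnorm(60)
  v <- v - mean(v) - cc * sum(v * cc) / sum(cc^2) + 5
  expect_lt(abs(sum((v - mean(v)) * cc)), 1e-8)
  s$expr$normalized["g002", ] <- v
  a2 <- adjust_for_covariates(s, "total_counts")
  expect_equal(unname(a2$expr$normalized["g002", ]), v, tolerance = 1e-8)

  # per-gene means preserved for every gene
  expect_equal(rowMeans(a2$expr$normalized), rowMeans(s$expr$normalized),
               tolerance = 1e-9)

  s$cells$flat <- rep(1, 60)
  expect_error(adjust_for_covariates(s, "flat"), "constant")
  s$cells$unique_factor <- paste0("lv", seq_len(60))
  expect_error(adjust_for_covariates(s, "unique_factor"), "levels")
})

test_that("HVG selection flags planted high-variability genes", {
  # constant genes carry no CoV signal
  s <- tiny_state(matrix(3, 40, 30))
  s$expr$normalized <- s$expr$raw
  s <- add_statistics(s)
  s <- find_hvg(s, "bins", n_bins = 4)
  expect_equal(sum(s$genes$hvg_flag), 0)

  # 200 background genes (CoV ~ 0.1) plus 10 with CoV inflated 5x, with
  # means spread over the same range so the planted genes land in
  # different expression bins
  set.seed(7)
  mu_bg <- runif(200, 5, 15)
  mu_hv <- runif(10, 5, 15)
  m <- rbind(
    matrix(rnorm(200 * 80, sd = 0.1), 200, 80) * mu_bg + mu_bg,
    matrix(rnorm(10 * 80, sd = 0.5), 10, 80) * mu_hv + mu_hv)
  dimnames(m) <- list(sprintf("g%03d", 1:210), sprintf("c%02d", 1:80))
  m <- abs(m)
  s2 <- tiny_state(m, coords = cbind(runif(80), runif(80)))
  s2$expr$normalized <- m
  s2 <- add_statistics(s2)
  s2 <- find_hvg(s2, "bins", n_bins = 20, z_threshold = 1.5)
  flagged <- s2$genes$gene_id[s2$genes$hvg_flag]
  expect_true(all(sprintf("g%03d", 201:210) %in% flagged))

  # flags are invariant under gene reordering
  set.seed(8)
  perm <- sample(210)
  s3 <- tiny_state(m[perm, ], coords = cbind(runif(80), runif(80)))
  s3$expr$normalized <- m[perm, ]
  s3 <- add_statistics(s3)
  s3 <- find_hvg(s3, "bins", n_bins = 20, z_threshold = 1.5)
  expect_setequal(s3$genes$gene_id[s3$genes$hvg_flag], flagged)

  expect_error(find_hvg(s2, "bins", n_bins = 211), "smaller n_bins")

  # loess variant runs and flags a superset-ish of strong signals
  s4 <- find_hvg(s2, "loess")
  expect_gt(sum(s4$genes$hvg_flag[201:210]), 5)
})

test_that("filter-normalize-statistics pipeline is idempotent", {
  s <- random_state(30, 50, seed = 9)
  p1 <- add_statistics(normalize_default(
    filter_dataset(s, 1, 2, 2)))
  p2 <- add_statistics(normalize_default(
    filter_dataset(p1, 1, 2, 2)))
  expect_equal(p2$expr$normalized, p1$expr$normalized)
  expect_equal(p2$cells$total_counts, p1$cells$total_counts)

  # with offset 1, per-cell sums of base^normalized - 1 all equal the
  # scale factor
  recon <- colSums(2^p1$expr$normalized - 1)
  expect_equal(unname(recon), rep(6000, ncol(p1$expr$raw)), tolerance = 1e-9)
})

test_that("expression neighbor graphs and community merging behave", {
  s <- random_state(10, 2, seed = 10)
  s <- normalize_default(s)
  g <- build_expression_neighbor_graph(s, k = 1)
  expect_equal(igraph::ecount(g), 1)
  expect_warning(build_expression_neighbor_graph(s, k = 5), "clamped")

  # sNN weights are bounded by k - 1 within a clique-ish neighborhood
  s2 <- random_state(10, 12, seed = 11)
  s2 <- normalize_default(s2)
  gs <- build_expression_neighbor_graph(s2, k = 4, shared = TRUE)
  expect_true(all(igraph::E(gs)$weight <= 4))

  # merging: two identical-profile clusters collapse
  m <- matrix(rnorm(20 * 40, 5), 20, 40,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:40)))
  m[, 21:40] <- m[, 1:20]
  sm <- tiny_state(abs(m), coords = cbind(runif(40), runif(40)))
  sm$expr$normalized <- m
  labs <- rep(c("a", "b"), each = 20)
  merged <- merge_similar_clusters(sm, labs, cor_threshold = 0.99)
  expect_equal(length(unique(merged)), 1)
  expect_error(merge_similar_clusters(sm, labs, cor_threshold = 1.2),
               "cor_threshold")

  # three clusters with one highly correlated pair merge exactly once
  set.seed(12)
  base <- rnorm(20)
  profs <- cbind(base, base + rnorm(20, sd = 0.15), rnorm(20))
  m3 <- matrix(0, 20, 30)
  for (k in 1:3) m3[, (k - 1) * 10 + 1:10] <-
      profs[, k] + rnorm(200, sd = 0.05)
  dimnames(m3) <- list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:30))
  s3 <- tiny_state(abs(m3), coords = cbind(runif(30), runif(30)))
  s3$expr$normalized <- m3
  labs3 <- rep(c("a", "b", "c"), each = 10)
  merged3 <- merge_similar_clusters(s3, labs3, cor_threshold = 0.9)
  expect_equal(length(unique(merged3)), 2)

  # community detection runs end to end on a graph
  cl <- cluster_communities(sm, graph = build_expression_neighbor_graph(
    sm, k = 4), method = "louvain", seed = 0)
  expect_equal(length(cl), 40)
})

test_that("state serialization round-trips through a TSV directory", {
  s <- random_state(12, 15, seed = 13)
  s <- normalize_default(s)
  s <- create_knn_network(s, k = 2)
  dir <- withr::local_tempdir()
  write_state(s, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  r <- read_state(dir)
  expect_equal(r$expr$raw, s$expr$raw)
  expect_equal(r$expr$normalized, s$expr$normalized, tolerance = 1e-9)
  expect_equal(nrow(r$networks$knn$edges), nrow(s$networks$knn$edges))
})
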