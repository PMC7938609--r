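test_that("proximity enrichment contrasts observed and permuted edge counts", {
  # single type: trivial homo pair with ratio 1
  s <- random_state(5, 30, seed = 70)
  s <- create_knn_network(s, k = 3)
  net <- s$networks$knn
  labs <- setNames(rep("a", 30), s$cells$cell_id)
  expect_warning(pe <- proximity_enrichment(net, labs, n_perm = 50, seed = 1),
                 "single cell type")
  expect_equal(pe$ratio, 1)
  expect_equal(pe$observed_edges, nrow(net$edges))

  # two types on disjoint halves: depleted hetero edges
  set.seed(71)
  co <- cbind(x = c(runif(100, 0, 40), runif(100, 60, 100)),
              y = runif(200, 0, 100))
  raw <- matrix(rpois(10 * 200, 3), 10, 200,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:200)))
  s2 <- create_spat_state(raw, co)
  s2 <- create_knn_network(s2, k = 4, max_dist = 15)
  labs2 <- setNames(rep(c("L", "R"), each = 100), s2$cells$cell_id)
  pe2 <- proximity_enrichment(s2$networks$knn, labs2, n_perm = 1000,
                              seed = 2)
  het <- pe2[pe2$pair_type == "hetero", ]
  expect_equal(het$observed_edges, 0)
  expect_equal(het$ratio, 0)
  expect_lte(het$p_lower, 0.01)

  # counts always decompose the edge total
  expect_equal(sum(pe2$observed_edges), nrow(s2$networks$knn$edges))
  # empirical p-values never hit zero
  expect_true(all(pe2$p_higher >= 1 / 1001 & pe2$p_lower >= 1 / 1001))
})

test_that("random labels give near-unit proximity ratios", {
  set.seed(72)
  s <- random_state(5, 400, seed = 72)
  s <- create_delaunay_network(s)
  labs <- setNames(sample(c("a", "b", "c"), 400, replace = TRUE),
                   s$cells$cell_id)
  pe <- proximity_enrichment(s$networks$delaunay, labs, n_perm = 500,
                             seed = 3)
  expect_true(all(pe$ratio > 0.8 & pe$ratio < 1.25))
  expect_gte(mean(pmin(pe$p_higher, pe$p_lower) > 0.05), 0.9)
})

lr_fixture <- function(seed = 73, n = 500, fold = 8) {
  ts <- simulate_layered_tissue(n_cells = n, n_types = 2, n_genes = 60,
                                n_markers_per_type = 5, marker_fold = 2,
                                layout = "layers", seed = seed,
                                width = 500, height = 500)
  ts <- create_delaunay_network(ts)
  ts <- plant_lr_effect(ts, ts$networks$delaunay, "type1", "type2",
                        "gene051", "gene052", fold = fold, seed = seed + 1)
  ts <- normalize_default(ts)
  ts
}

test_that("spatially confined ligand-receptor pairs are detected and the
           expression-only score is attenuated", {
  ts <- lr_fixture()
  labs <- ts$results$simulation_truth$labels
  net <- ts$networks$delaunay
  lrdb <- data.frame(ligand = c("gene051", "gene001"),
                     receptor = c("gene052", "gene002"))
  sp <- spatial_lr_communication(ts, net, labs, lrdb, n_perm = 1000,
                                 seed = 4)
  ex <- expression_lr_communication(ts, labs, lrdb, n_perm = 1000, seed = 5)
  key <- function(d) d$ligand == "gene051" & d$type_a == "type1" &
    d$type_b == "type2"
  expect_lte(sp$adjusted_p[key(sp)], 0.05)
  expect_gt(sp$log2fc[key(sp)], 0)
  expect_lt(ex$log2fc[key(ex)], sp$log2fc[key(sp)])

  # constant ligand/receptor scores are permutation-invariant
  flat <- ts
  flat$expr$normalized["gene001", ] <- 2
  flat$expr$normalized["gene002", ] <- 3
  spf <- spatial_lr_communication(flat, net, labs,
                                  data.frame(ligand = "gene001",
                                             receptor = "gene002"),
                                  n_perm = 200, seed = 6)
  expect_equal(spf$log2fc, rep(0, nrow(spf)), tolerance = 1e-9)
  expect_true(all(spf$p_value > 0.9))

  # S recomputes from the stored interacting subsets
  r <- sp[key(sp), ]
  nbr <- spatkit:::.adjacency_list(net, ncol(ts$expr$raw))
  intA <- spatkit:::.interacting_cells(nbr, unname(labs), "type1", "type2")
  intB <- spatkit:::.interacting_cells(nbr, unname(labs), "type2", "type1")
  S <- mean(ts$expr$normalized["gene051", intA]) +
    mean(ts$expr$normalized["gene052", intB])
  expect_equal(r$S, S, tolerance = 1e-12)
  expect_equal(r$n, length(intA))
})

test_that("never-adjacent type pairs produce no communication rows", {
  set.seed(74)
  co <- cbind(x = c(runif(40, 0, 10), runif(40, 90, 100)), y = runif(80, 0, 10))
  raw <- matrix(rpois(10 * 80, 5) + 1, 10, 80,
                dimnames = list(paste0("g", 1:10), paste0("c", 1:80)))
  s <- create_spat_state(raw, co,
                         annotations = data.frame(
                           cell_type = rep(c("a", "b"), each = 40)))
  s <- create_knn_network(s, k = 3, max_dist = 20)
  s <- normalize_default(s)
  labs <- setNames(s$cells$cell_type, s$cells$cell_id)
  sp <- spatial_lr_communication(s, s$networks$knn, labs,
                                 data.frame(ligand = "g1", receptor = "g2"),
                                 n_perm = 100, seed = 7)
  expect_false(any(sp$type_a == "a" & sp$type_b == "b"))
})

test_that("ranking comparison AUC spans identical to reversed orderings", {
  base <- data.frame(ligand = rep(paste0("L", 1:20), 2),
                     receptor = rep(paste0("R", 1:20), 2),
                     type_a = rep(c("a", "b"), each = 20),
                     type_b = rep(c("b", "a"), each = 20),
                     activity_score = c(20:1, 1:20))
  same <- compare_communication_rankings(base, base)
  expect_equal(same$auc, 1)
  rev <- base
  rev$activity_score <- -rev$activity_score
  expect_equal(compare_communication_rankings(base, rev)$auc, 0)

  # independent random scores over many type pairs land near 1/2
  set.seed(75)
  big <- data.frame(ligand = rep(paste0("L", 1:20), 50),
                    receptor = rep(paste0("R", 1:20), 50),
                    type_a = rep(paste0("t", 1:50), each = 20),
                    type_b = "x",
                    activity_score = rnorm(1000))
  big2 <- big
  big2$activity_score <- rnorm(1000)
  a <- compare_communication_rankings(big, big2)$auc
  expect_true(a > 0.4 && a < 0.6)
  expect_error(compare_communication_rankings(base[0, ], base), "no shared")
})

test_that("interaction changed genes are recovered from a planted shift", {
  ts <- simulate_layered_tissue(n_cells = 800, n_types = 3, n_genes = 100,
                                n_markers_per_type = 5, marker_fold = 2,
                                layout = "layers", seed = 76,
                                width = 800, height = 800)
  ts <- create_delaunay_network(ts)
  icg_genes <- sprintf("gene%03d", 91:100)
  ts <- plant_icg_effect(ts, ts$networks$delaunay, "type2", "type3",
                         icg_genes, fold = 4, seed = 77)
  ts <- normalize_default(ts)
  labs <- ts$results$simulation_truth$labels
  icg <- find_icg(ts, ts$networks$delaunay, labs, test = "t")
  blk <- icg[icg$source_type == "type2" & icg$neighbor_type == "type3", ]
  planted <- blk[blk$gene %in% icg_genes, ]
  expect_true(all(planted$adjusted_p < 0.1))
  expect_true(all(planted$log2fc > 1))
  expect_equal(planted$n_with + planted$n_without,
               rep(sum(labs == "type2"), nrow(planted)))

  # t-test and permutation test agree in sign on nearly all genes
  icg_p <- find_icg(ts, ts$networks$delaunay, labs, test = "permutation",
                    n_perm = 200, seed = 78)
  blk_p <- icg_p[icg_p$source_type == "type2" &
                   icg_p$neighbor_type == "type3", ]
  agree <- sign(blk$statistic) == sign(blk_p$statistic)
  expect_gte(mean(agree[blk$statistic != 0]), 0.99)

  # wilcoxon variant runs and flags the planted genes too
  icg_w <- find_icg(ts, ts$networks$delaunay, labs, test = "wilcoxon")
  blk_w <- icg_w[icg_w$source_type == "type2" &
                   icg_w$neighbor_type == "type3", ]
  expect_true(all(blk_w$adjusted_p[blk_w$gene %in% icg_genes] < 0.1))
})

test_that("null ICG comparisons yield no significant genes", {
  ts <- simulate_layered_tissue(n_cells = 600, n_types = 3, n_genes = 80,
                                marker_fold = 1, n_markers_per_type = 5,
                                layout = "random", seed = 79)
  ts <- create_delaunay_network(ts)
  ts <- normalize_default(ts)
  labs <- ts$results$simulation_truth$labels
  icg <- find_icg(ts, ts$networks$delaunay, labs, test = "t")
  expect_lte(mean(icg$adjusted_p < 0.05), 0.02)
})

test_that("ICG filtering applies all four row predicates", {
  tab <- data.frame(
    gene = paste0("g", 1:4),
    source_type = "a", neighbor_type = "b",
    n_with = c(10, 2, 10, 10), n_without = c(20, 20, 20, 20),
    mean_with = c(5, 5, 0.1, 5), mean_without = c(1, 1, 0.01, 1),
    log2fc = c(2.5, 2.5, 2.5, 0.5),
    statistic = 1, p_value = c(0.001, 0.001, 0.001, 0.001),
    adjusted_p = c(0.01, 0.01, 0.01, 0.01))
  # thresholds at their neutral values keep everything
  expect_equal(nrow(filter_icg(tab)), 4)
  out <- filter_icg(tab, min_cells = 5, min_fdr = 0.05, min_log2fc = 2,
                    min_expr = 1)
  expect_equal(out$gene, "g1")
  # min_cells above every subgroup empties the table
  expect_equal(nrow(filter_icg(tab, min_cells = 100)), 0)
})

test_that("a neighbor type absent from the tissue produces no block", {
  s <- random_state(20, 60, seed = 80)
  s <- normalize_default(s)
  s <- create_knn_network(s, k = 3)
  labs <- setNames(rep(c("a", "b"), each = 30), s$cells$cell_id)
  icg <- find_icg(s, s$networks$knn, labs, test = "t")
  expect_true(all(icg$neighbor_type %in% c("a", "b")))
  expect_gt(nrow(icg), 0)
})
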