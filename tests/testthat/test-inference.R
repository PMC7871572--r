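test_that("correlation engine matches the sum-of-products formula", {
  set.seed(10)
  expr <- random_expression(6, 30)
  regs <- c("g1", "g2")
  el <- pcc_network(expr, regs)
  for (e in seq_len(nrow(el))) {
    expect_equal(el$confidence[e],
                 abs(oracle_pearson(expr[el$regulator[e], ], expr[el$target[e], ])),
                 tolerance = 1e-12)
  }
  # identical profiles share the top rank with |r| = 1
  expr2 <- expr
  expr2["g3", ] <- expr2["g1", ]
  el2 <- pcc_network(expr2, regs)
  expect_equal(el2$confidence[1], 1.0)
  expect_true("g3" %in% el2$target[el2$confidence == el2$confidence[1]])
})

test_that("constant profiles give zero-confidence edges with a warning", {
  set.seed(11)
  expr <- random_expression(5, 20)
  expr["g1", ] <- 3
  expect_warning(el <- pcc_network(expr, c("g1", "g2")), "zero-variance")
  expect_true(all(el$confidence[el$regulator == "g1"] == 0))
})

test_that("plug-in mutual information matches a hand-coded estimator", {
  set.seed(12)
  expr <- random_expression(3, 40)
  mi <- mutual_information_matrix(expr, c("g1", "g2"), bins = 4)
  for (i in rownames(mi)) {
    for (j in colnames(mi)) {
      bi <- ceiling(rank(expr[i, ], ties.method = "first") * 4 / 40)
      bj <- ceiling(rank(expr[j, ], ties.method = "first") * 4 / 40)
      expect_equal(mi[i, j], oracle_mi(bi, bj, 4), tolerance = 1e-12)
    }
  }
  # regulator x regulator block is symmetric, all entries non-negative
  expect_equal(mi["g1", "g2"], mi["g2", "g1"], tolerance = 1e-12)
  expect_true(all(mi >= 0))
})

test_that("MI of a profile with itself is the binned entropy", {
  set.seed(13)
  expr <- random_expression(2, 50)  # 50 samples divide evenly into 10 bins
  mi <- mutual_information_matrix(expr, c("g1", "g2"), bins = 10)
  expect_equal(mi["g1", "g1"], log(10), tolerance = 1e-12)
})

test_that("MI of independent profiles is near zero at large n", {
  set.seed(14)
  expr <- random_expression(2, 1000)
  mi <- mutual_information_matrix(expr, "g1", bins = 10)
  expect_lt(mi["g1", "g2"], 0.1)
})

test_that("MI estimation rejects fewer samples than bins", {
  expr <- random_expression(3, 5, seed = 15)
  expect_error(mutual_information_matrix(expr, "g1", bins = 10), "fewer samples")
})

test_that("CLR confidences match a brute-force z-score recomputation", {
  set.seed(16)
  expr <- random_expression(5, 40)
  regs <- c("g1", "g2", "g3")
  mi <- mutual_information_matrix(expr, regs, bins = 5)
  el <- clr_network(expr, regs, bins = 5)
  for (e in seq_len(nrow(el))) {
    expect_equal(el$confidence[e],
                 oracle_clr_confidence(mi, el$regulator[e], el$target[e]),
                 tolerance = 1e-12)
  }
})

test_that("CLR yields all-zero confidences when every MI value is equal", {
  # two identical uniform-grid profiles in different order: every pairwise
  # MI equals the entropy, so background-corrected z-scores vanish
  expr <- matrix(c(1:8, 8:1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  el <- clr_network(expr, c("g1", "g2"), bins = 2)
  expect_true(all(el$confidence == 0))
})

test_that("DPI pruning removes the weakest edge of a chain triangle", {
  # x -> y -> z with independent noise: MI(x,z) is smallest in its triangle
  set.seed(17)
  n <- 400
  x <- rnorm(n); y <- x + rnorm(n, 0, 0.6); z <- y + rnorm(n, 0, 0.6)
  expr <- rbind(x = x, y = y, z = z)
  colnames(expr) <- paste0("s", 1:n)
  mi <- mutual_information_matrix(expr, c("x", "y"), bins = 8)
  expect_lt(mi["x", "z"], min(mi["x", "y"], mi["y", "z"]))
  el <- aracne_network(expr, c("x", "y"), bins = 8, dpi_tolerance = 0)
  expect_false(any(el$regulator == "x" & el$target == "z"))
  expect_true(any(el$regulator == "x" & el$target == "y"))
  expect_true(any(el$regulator == "y" & el$target == "z"))
})

test_that("DPI at full tolerance keeps every edge, ranked purely by MI", {
  set.seed(18)
  expr <- random_expression(6, 40)
  regs <- c("g1", "g2", "g3")
  el <- aracne_network(expr, regs, bins = 5, dpi_tolerance = 1)
  mi <- mutual_information_matrix(expr, regs, bins = 5)
  expect_equal(nrow(el), length(regs) * (nrow(expr) - 1))
  expect_equal(el$confidence, sort(mi[cbind(el$regulator, el$target)],
                                   decreasing = TRUE),
               tolerance = 0)
})

test_that("DPI pruning matches exhaustive triangle enumeration", {
  for (seed in c(19, 20, 21)) {
    set.seed(seed)
    expr <- random_expression(8, 60)
    regs <- c("g1", "g2", "g3", "g4")
    tol <- sample(c(0, 0.1, 0.3), 1)
    mi <- mutual_information_matrix(expr, regs, bins = 5)
    removed <- oracle_dpi_removed(mi, tol)
    el <- aracne_network(expr, regs, bins = 5, dpi_tolerance = tol)
    emitted <- matrix(FALSE, length(regs), nrow(expr), dimnames = dimnames(mi))
    emitted[cbind(el$regulator, el$target)] <- TRUE
    for (r in regs) {
      for (g in rownames(expr)) {
        expect_identical(emitted[r, g], r != g && !removed[r, g],
                         label = sprintf("seed %d edge %s->%s", seed, r, g))
      }
    }
  }
})

test_that("tree-ensemble engine recovers a copied regulator under fixed seed", {
  set.seed(22)
  n <- 60
  expr <- random_expression(7, n)
  expr["g7", ] <- expr["g1", ]  # target g7 identically equals regulator g1
  regs <- paste0("g", 1:6)
  el <- genie3_network(expr, regs, n_trees = 100, seed = 5)
  g7_edges <- el[el$target == "g7", ]
  expect_identical(g7_edges$regulator[1], "g1")
  # per-target normalisation: importances for each target sum to 1
  for (tgt in unique(el$target)) {
    expect_equal(sum(el$confidence[el$target == tgt]), 1, tolerance = 1e-9)
  }
})

test_that("tree-ensemble importances are diffuse for pure-noise targets", {
  set.seed(23)
  expr <- random_expression(8, 80)
  regs <- paste0("g", 1:6)
  el <- genie3_network(expr, regs, n_trees = 200, seed = 7)
  noise_edges <- el[el$target == "g8", ]
  expect_lt(max(noise_edges$confidence), 0.5)
})

test_that("tree-ensemble engine is deterministic given its seed", {
  expr <- random_expression(5, 30, seed = 24)
  regs <- c("g1", "g2", "g3")
  a <- genie3_network(expr, regs, n_trees = 50, seed = 9)
  b <- genie3_network(expr, regs, n_trees = 50, seed = 9)
  expect_identical(a, b)
})

test_that("bootstrap elastic-net confidences are selection frequencies", {
  set.seed(25)
  expr <- random_expression(5, 40)
  regs <- c("g1", "g2", "g3")
  el <- elasticnet_network(expr, regs, n_bootstrap = 20, seed = 3)
  expect_true(all(el$confidence >= 0 & el$confidence <= 1))
  # a single resample forces frequencies into {0, 1}
  el1 <- elasticnet_network(expr, regs, n_bootstrap = 1, seed = 3)
  expect_true(all(el1$confidence %in% c(0, 1)))
})

test_that("a noiseless proportional target is selected on every resample", {
  set.seed(26)
  expr <- random_expression(5, 40)
  expr["g5", ] <- 2 * expr["g1", ]
  regs <- c("g1", "g2")
  el <- elasticnet_network(expr, regs, n_bootstrap = 25, seed = 4)
  expect_equal(el$confidence[el$regulator == "g1" & el$target == "g5"], 1.0)
})

test_that("stability-selection area scores stay in [0, 1] and find the driver", {
  set.seed(27)
  n <- 60
  expr <- random_expression(6, n)
  expr["g6", ] <- expr["g1", ] + rnorm(n, 0, 0.05)
  regs <- paste0("g", 1:5)
  el <- tigress_network(expr, regs, n_resample = 20, lars_steps = 3, seed = 6)
  expect_true(all(el$confidence >= 0 & el$confidence <= 1))
  g6 <- el[el$target == "g6", ]
  # the dominant driver holds the maximum area score for its target
  expect_identical(g6$regulator[which.max(g6$confidence)], "g1")
  expect_gt(max(g6$confidence), 0.9)
})

test_that("stability selection validates its resampling parameters", {
  expr <- random_expression(4, 20, seed = 28)
  regs <- c("g1", "g2", "g3")
  expect_error(tigress_network(expr, regs, n_resample = 3), "even")
  expect_error(tigress_network(expr, regs, lars_steps = 3, n_resample = 4),
               "lars_steps")
})

test_that("every engine emits a valid ranked edge list on a common fixture", {
  expr <- random_expression(6, 40, seed = 29)
  regs <- c("g1", "g2", "g3")
  nets <- run_engines(expr, regs, c("pcc", "clr", "aracne"), seed = 1)
  nets <- c(nets, run_engines(expr, regs, "genie3", seed = 1,
                              config = list(n_trees = 50)))
  nets <- c(nets, run_engines(expr, regs, "elasticnet", seed = 1,
                              config = list(n_bootstrap = 10)))
  nets <- c(nets, run_engines(expr, regs, "tigress", seed = 1,
                              config = list(n_resample = 4, lars_steps = 2)))
  for (nm in names(nets)) {
    el <- nets[[nm]]
    expect_s3_class(el, "ranked_edges")
    expect_true(all(diff(el$confidence) <= 0), label = nm)
    expect_false(any(el$regulator == el$target), label = nm)
    expect_true(all(el$regulator %in% regs), label = nm)
    expect_false(anyDuplicated(paste(el$regulator, el$target)) > 0, label = nm)
  }
})
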