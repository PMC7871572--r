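# Fixture with two blocks of mutually correlated genes plus a few unattached
# noise genes; used for module detection and recovery checks. The two latent
# factors share a mild positive correlation (as co-expression modules in one
# tissue usually do) so the merge rule has a well-defined direction.
planted_blocks <- function(n_per_block = 20, n_noise = 6, n_samples = 100,
                           within_cor = 0.9, between = 0.3, seed = 50) {
  set.seed(seed)
  lat1 <- rnorm(n_samples)
  lat2 <- between * lat1 + sqrt(1 - between^2) * rnorm(n_samples)
  noise_sd <- sqrt(1 / within_cor^2 - 1)
  block1 <- t(sapply(seq_len(n_per_block), function(i)
    lat1 + rnorm(n_samples, 0, noise_sd)))
  block2 <- t(sapply(seq_len(n_per_block), function(i)
    lat2 + rnorm(n_samples, 0, noise_sd)))
  noise <- matrix(rnorm(n_noise * n_samples), nrow = n_noise)
  expr <- rbind(block1, block2, noise)
  rownames(expr) <- c(paste0("b1_", seq_len(n_per_block)),
                      paste0("b2_", seq_len(n_per_block)),
                      paste0("nz_", seq_len(n_noise)))
  colnames(expr) <- paste0("s", seq_len(n_samples))
  expr
}

test_that("soft adjacency matches |cor|^power elementwise", {
  expr <- random_expression(7, 30, seed = 51)
  a <- wgcna_adjacency(expr, power = 6)
  cc <- cor(t(expr))
  for (i in 1:7) for (j in 1:7) {
    expect_equal(a[i, j], if (i == j) 1 else abs(cc[i, j])^6, tolerance = 1e-12)
  }
  expect_true(all(a >= 0 & a <= 1))
  # degenerate corners
  expr2 <- expr; expr2[2, ] <- expr2[1, ]
  a2 <- wgcna_adjacency(expr2, 6)
  expect_equal(a2[1, 2], 1)
  expr3 <- expr; expr3[3, ] <- 5
  expect_warning(a3 <- wgcna_adjacency(expr3, 6), "zero-variance")
  expect_true(all(a3[3, -3] == 0))
})

test_that("topological overlap matches a triple-loop brute force", {
  set.seed(52)
  cc <- cor(t(random_expression(6, 25)))
  a <- abs(cc)^3; diag(a) <- 1
  tom <- topological_overlap(a)
  expect_equal(tom, oracle_tom(a), tolerance = 1e-12)
  expect_equal(tom, t(tom), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1))
  # direct-term lower bound
  k <- rowSums(a) - 1
  for (i in 1:6) for (j in 1:6) {
    if (i == j) next
    expect_gte(tom[i, j], a[i, j] / (min(k[i], k[j]) + 1 - a[i, j]) - 1e-12)
  }
})

test_that("topological overlap hits its boundary cases", {
  # identical binary neighbourhoods with a_ij = 1: maximal overlap, TOM = 1
  a <- matrix(c(1, 1, 1,
                1, 1, 1,
                1, 1, 1), nrow = 3, byrow = TRUE)
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 1, tolerance = 1e-12)
  # disconnected pair with no shared neighbours -> TOM = 0
  b <- diag(4); b[1, 2] <- b[2, 1] <- 0.8
  tom2 <- topological_overlap(b)
  expect_equal(tom2[3, 4], 0)
})

test_that("module eigengene matches the spectral oracle and sign rule", {
  set.seed(53)
  common <- rnorm(40)
  expr <- rbind(m1 = common, m2 = common, m3 = common,
                other = rnorm(40))
  colnames(expr) <- paste0("s", 1:40)
  me <- module_eigengene(expr, c("m1", "m2", "m3"))
  expect_equal(cor(me, common), 1, tolerance = 1e-9)
  expect_equal(sd(me), 1, tolerance = 1e-9)
  # mixed-orientation module: the mean rule aligns the eigengene with the
  # majority orientation, leaving the anticorrelated member negative
  expr2 <- rbind(p1 = common + rnorm(40, 0, 0.2),
                 p2 = common + rnorm(40, 0, 0.2),
                 q = -common + rnorm(40, 0, 0.2))
  colnames(expr2) <- paste0("s", 1:40)
  me2 <- module_eigengene(expr2, c("p1", "p2", "q"))
  expect_gt(cor(expr2["p1", ], me2), 0)
  expect_gt(cor(expr2["p2", ], me2), 0)
  expect_lt(cor(expr2["q", ], me2), 0)
  # random module: matches eigen-decomposition of the covariance up to sign
  set.seed(54)
  expr3 <- random_expression(5, 30)
  me3 <- module_eigengene(expr3, rownames(expr3))
  z <- t(scale(t(expr3)))
  ev <- eigen(t(z) %*% z)$vectors[, 1]
  ev <- ev / sd(ev)
  expect_equal(abs(cor(me3, ev)), 1, tolerance = 1e-8)
})

test_that("module detection recovers planted blocks and obeys its limits", {
  expr <- planted_blocks()
  a <- wgcna_adjacency(expr, 6)
  tom <- topological_overlap(a)
  mod <- detect_modules(tom, expr, min_module_size = 5)
  labs <- mod$labels
  expect_equal(length(mod$eigengenes), 2L)
  b1 <- labs[paste0("b1_", 1:20)]; b2 <- labs[paste0("b2_", 1:20)]
  maj1 <- as.integer(names(which.max(table(b1))))
  maj2 <- as.integer(names(which.max(table(b2))))
  expect_true(maj1 > 0 && maj2 > 0 && maj1 != maj2)
  recovery <- (sum(b1 == maj1) + sum(b2 == maj2)) / 40
  expect_gte(recovery, 0.95)
  # near-total merge threshold collapses the blocks into one module
  mod1 <- detect_modules(tom, expr, min_module_size = 5,
                         merge_threshold = 0.999)
  expect_equal(length(mod1$eigengenes), 1L)
  # oversized minimum module size leaves everything unassigned
  expect_error(detect_modules(tom, expr, min_module_size = 50L),
               "unassigned")
})

test_that("soft-power selection reaches the scale-free target on hub data", {
  # single-factor design with heavy-tailed membership weights: connectivity
  # follows a power law, the regime the fit index is built for
  set.seed(60)
  n <- 200; ns <- 100
  w <- runif(n)^2
  f <- rnorm(ns)
  expr <- t(sapply(seq_len(n), function(i)
    w[i] * f + sqrt(1 - w[i]^2) * rnorm(ns)))
  rownames(expr) <- paste0("g", 1:n); colnames(expr) <- paste0("s", 1:ns)
  p <- pick_soft_power(expr, powers = 1:10, fit_target = 0.8)
  fit <- grnhubs:::scale_free_fit(wgcna_adjacency(expr, p))
  expect_gte(fit, 0.8)
  # vacuous criterion returns the smallest candidate
  expr <- planted_blocks(seed = 55)
  expect_equal(pick_soft_power(expr, powers = 3:8, fit_target = -1), 3L)
  # constant matrix is degenerate
  flat <- matrix(1, 5, 10, dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expect_error(suppressWarnings(pick_soft_power(flat, powers = 2)), "degenerate")
})

test_that("kME ranking scores regulators by eigengene membership", {
  expr <- planted_blocks(seed = 56)
  fit <- wgcna_hub_ranking(expr, regulators = c("b1_1", "b2_1", "nz_1"),
                           power = 6, min_module_size = 5)
  expect_gt(fit$scores[["b1_1"]], 0.8)
  expect_gt(fit$scores[["b2_1"]], 0.8)
  # block members outrank the unattached noise regulator
  expect_identical(fit$ranking[3], "nz_1")
  # a pure-noise regulator at large n has low membership everywhere
  set.seed(57)
  expr_big <- planted_blocks(n_samples = 1000, seed = 57)
  fitn <- wgcna_hub_ranking(expr_big, regulators = c("b1_1", "nz_1"),
                            power = 6, min_module_size = 5)
  expect_lt(fitn$scores[["nz_1"]], 0.2)
  # scores match brute-force correlations with the assigned eigengene
  labs <- fit$modules$labels
  lab <- labs[["b1_1"]]
  expect_equal(fit$scores[["b1_1"]],
               abs(cor(expr["b1_1", ], fit$modules$eigengenes[[as.character(lab)]])),
               tolerance = 1e-12)
})
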