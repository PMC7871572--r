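# The six bundled GRN inference engines. Each maps (expression matrix,
# regulator set) to a ranked edge list of directed regulator -> target edges.
# Candidate targets are all genes in the matrix; a regulator is never its own
# target. Correlation and mutual-information engines work on raw profiles
# (they are rank/affine robust); the regression engines standardise profiles
# internally because their penalties are scale-sensitive.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so engines never perturb each other's streams.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

check_engine_input <- function(expr, regulators) {
  expr <- validate_expression(expr)
  regulators <- unique(as.character(regulators))
  if (!length(regulators)) stop("regulator set is empty")
  missing <- setdiff(regulators, rownames(expr))
  if (length(missing))
    stop("regulator(s) not in expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  list(expr = expr, regulators = regulators)
}

# Flatten a regulators x genes confidence matrix into a ranked edge list,
# dropping self-pairs.
edges_from_matrix <- function(conf, regulators, genes, method) {
  reg <- rep(regulators, times = length(genes))
  tgt <- rep(genes, each = length(regulators))
  keep <- reg != tgt
  ranked_edge_list(reg[keep], tgt[keep], as.vector(conf)[keep], method = method)
}

#' Absolute-correlation network
#'
#' Edge confidence is the absolute Pearson correlation between the regulator
#' and target expression profiles. Zero-variance profiles have undefined
#' correlation; their edges get confidence 0 and a warning is issued.
#'
#' @param expr Genes x samples numeric matrix (see [read_expression()]).
#' @param regulators Character vector of candidate regulator gene ids; all
#'   must occur in `rownames(expr)`.
#' @return A `ranked_edges` data.frame.
#' @export
pcc_network <- function(expr, regulators) {
  inp <- check_engine_input(expr, regulators)
  expr <- inp$expr; regulators <- inp$regulators
  if (ncol(expr) < 3L) stop("need at least 3 samples for correlation")
  conf <- abs(suppressWarnings(
    stats::cor(t(expr[regulators, , drop = FALSE]), t(expr))))
  if (anyNA(conf)) {
    warning("zero-variance profile(s): affected edges get confidence 0")
    conf[is.na(conf)] <- 0
  }
  edges_from_matrix(conf, regulators, rownames(expr), "pcc")
}

# Equal-frequency bin labels in 1..bins (ties broken by sample order so bin
# occupancies are as equal as possible).
equal_freq_bins <- function(x, bins) {
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * bins / n))
}

plugin_mi <- function(bi, bj, bins) {
  n <- length(bi)
  joint <- tabulate((bi - 1L) * bins + bj, nbins = bins * bins) / n
  pi_ <- tabulate(bi, nbins = bins) / n
  pj_ <- tabulate(bj, nbins = bins) / n
  pp <- outer(pj_, pi_)  # column-major layout of `joint`
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pp[nz]))
}

#' Mutual-information matrix (regulators x genes)
#'
#' MI is estimated by equal-frequency discretisation into `bins` bins followed
#' by the maximum-likelihood plug-in estimator on the 2-D contingency table,
#' in nats. The diagonal-like entries `MI(x, x)` equal the discretised entropy
#' (`log(bins)` when the sample count divides evenly into the bins).
#'
#' @inheritParams pcc_network
#' @param bins Number of equal-frequency bins (>= 2; also <= sample count).
#' @return Numeric matrix, rows = regulators, columns = all genes; all
#'   entries >= 0 and symmetric on the regulator x regulator block.
#' @export
mutual_information_matrix <- function(expr, regulators, bins = 10L) {
  inp <- check_engine_input(expr, regulators)
  expr <- inp$expr; regulators <- inp$regulators
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2")
  if (ncol(expr) < bins) stop("fewer samples (", ncol(expr), ") than bins (", bins, ")")
  binned <- t(apply(expr, 1L, equal_freq_bins, bins = bins))
  genes <- rownames(expr)
  mi <- matrix(0, nrow = length(regulators), ncol = length(genes),
               dimnames = list(regulators, genes))
  for (i in seq_along(regulators)) {
    bi <- binned[regulators[i], ]
    for (j in seq_along(genes)) {
      mi[i, j] <- plugin_mi(bi, binned[j, ], bins)
    }
  }
  mi
}

#' CLR network (context likelihood of relatedness)
#'
#' Background-corrects each mutual-information value against its row and
#' column distributions: `z_i = max(0, (MI_ij - mean_i) / sd_i)` over the
#' regulator's row, `z_j` likewise over the gene's column, and the edge
#' confidence is `sqrt(z_i^2 + z_j^2)`. Rows or columns with zero spread
#' contribute z = 0.
#'
#' @inheritParams mutual_information_matrix
#' @export
clr_network <- function(expr, regulators, bins = 10L) {
  mi <- mutual_information_matrix(expr, regulators, bins)
  rmu <- rowMeans(mi); rsd <- apply(mi, 1L, stats::sd)
  cmu <- colMeans(mi); csd <- apply(mi, 2L, stats::sd)
  zr <- (mi - rmu) / ifelse(rsd > 0, rsd, Inf)
  zc <- sweep(sweep(mi, 2L, cmu), 2L, ifelse(csd > 0, csd, Inf), `/`)
  zr <- pmax(zr, 0); zc <- pmax(zc, 0)
  conf <- sqrt(zr^2 + zc^2)
  edges_from_matrix(conf, rownames(mi), colnames(mi), "clr")
}

#' ARACNE network (data-processing-inequality pruning)
#'
#' Starts from the full mutual-information edge set and, for every triangle
#' whose three MI values are all available (two regulators and any third
#' gene), removes the weakest edge when its MI falls strictly below
#' `(1 - dpi_tolerance)` times the smaller of the other two. All triangles are
#' judged against the original MI matrix. Surviving edges are ranked by MI.
#'
#' @inheritParams mutual_information_matrix
#' @param dpi_tolerance Tolerance in `[0, 1]`; 0 prunes aggressively, 1
#'   disables pruning entirely.
#' @export
aracne_network <- function(expr, regulators, bins = 10L, dpi_tolerance = 0) {
  if (dpi_tolerance < 0 || dpi_tolerance > 1) stop("dpi_tolerance must be in [0, 1]")
  mi <- mutual_information_matrix(expr, regulators, bins)
  regulators <- rownames(mi); genes <- colnames(mi)
  R <- length(regulators)
  removed <- matrix(FALSE, nrow = R, ncol = length(genes),
                    dimnames = dimnames(mi))
  fac <- 1 - dpi_tolerance
  reg_col <- match(regulators, genes)
  if (R >= 2L) {
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        m_ij <- mi[i, reg_col[j]]
        g <- which(genes != regulators[i] & genes != regulators[j])
        m_ig <- mi[i, g]; m_jg <- mi[j, g]
        rm_ig <- m_ig < fac * pmin(m_jg, m_ij)
        rm_jg <- m_jg < fac * pmin(m_ig, m_ij)
        rm_ij <- any(m_ij < fac * pmin(m_ig, m_jg))
        removed[i, g[rm_ig]] <- TRUE
        removed[j, g[rm_jg]] <- TRUE
        if (rm_ij) {
          removed[i, reg_col[j]] <- TRUE
          removed[j, reg_col[i]] <- TRUE
        }
      }
    }
  }
  reg <- rep(regulators, times = length(genes))
  tgt <- rep(genes, each = R)
  keep <- reg != tgt & !as.vector(removed)
  ranked_edge_list(reg[keep], tgt[keep], as.vector(mi)[keep], method = "aracne")
}

resolve_mtry <- function(feature_fraction, p) {
  if (identical(feature_fraction, "sqrt")) return(max(1L, floor(sqrt(p))))
  if (identical(feature_fraction, "all")) return(p)
  frac <- as.numeric(feature_fraction)
  if (is.na(frac) || frac <= 0 || frac > 1)
    stop("tree_feature_fraction must be 'sqrt', 'all', or a fraction in (0, 1]")
  max(1L, floor(frac * p))
}

#' Tree-ensemble network (GENIE3-style)
#'
#' For each target gene a random-forest regression of the target's profile on
#' all regulator profiles (excluding the target itself) is fitted with
#' [ranger::ranger()]; the confidence of edge (regulator, target) is the
#' regulator's total variance-reduction (impurity) importance, normalised per
#' target so each target's importances sum to 1. Constant targets yield all-0
#' importances and a warning.
#'
#' @inheritParams pcc_network
#' @param n_trees Trees per target forest.
#' @param feature_fraction Features tried per split: `"sqrt"`, `"all"`, or a
#'   fraction in `(0, 1]` of the candidate regulators.
#' @param seed Integer seed; the engine is deterministic given it.
#' @export
genie3_network <- function(expr, regulators, n_trees = 1000L,
                           feature_fraction = "sqrt", seed = 1L) {
  inp <- check_engine_input(expr, regulators)
  expr <- inp$expr; regulators <- inp$regulators
  if (length(regulators) < 2L) stop("need at least 2 regulators")
  genes <- rownames(expr)
  conf <- matrix(0, nrow = length(regulators), ncol = length(genes),
                 dimnames = list(regulators, genes))
  warned <- FALSE
  for (j in seq_along(genes)) {
    tgt <- genes[j]
    feats <- setdiff(regulators, tgt)
    y <- expr[tgt, ]
    if (stats::sd(y) == 0) { warned <- TRUE; next }
    x <- as.data.frame(t(expr[feats, , drop = FALSE]))
    colnames(x) <- feats
    fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                          mtry = resolve_mtry(feature_fraction, length(feats)),
                          importance = "impurity", num.threads = 1L,
                          seed = seed + j)
    imp <- pmax(fit$variable.importance, 0)
    s <- sum(imp)
    if (s > 0) conf[feats, j] <- imp / s
  }
  if (warned) warning("constant target profile(s): importances set to 0")
  edges_from_matrix(conf, regulators, genes, "genie3")
}

standardize_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  sd[sd == 0] <- 1
  (m - mu) / sd
}

# Pick one elastic-net penalty per target on the full data by BIC over the
# glmnet path, held fixed across bootstrap resamples so the reported
# confidence stays a pure selection frequency.
select_lambda_bic <- function(x, y, alpha) {
  fit <- glmnet::glmnet(x, y, alpha = alpha, standardize = FALSE,
                        intercept = FALSE)
  pred <- stats::predict(fit, newx = x)
  n <- length(y)
  rss <- colSums((y - pred)^2)
  bic <- n * log(pmax(rss, 1e-12) / n) + fit$df * log(n)
  fit$lambda[which.min(bic)]
}

#' Bootstrap elastic-net network
#'
#' For each target, an elastic-net linear model of the (standardised) target
#' on the standardised regulator profiles is fitted on each of `n_bootstrap`
#' bootstrap resamples of the samples; the edge confidence is the fraction of
#' resamples in which the regulator's coefficient is nonzero. The penalty is
#' chosen once per target on the full data (BIC over the path) and held fixed
#' across resamples.
#'
#' @inheritParams genie3_network
#' @param n_bootstrap Number of bootstrap resamples (>= 1).
#' @param l1_ratio Elastic-net mixing parameter in `(0, 1]` (1 = lasso).
#' @export
elasticnet_network <- function(expr, regulators, n_bootstrap = 1000L,
                               l1_ratio = 0.5, seed = 1L) {
  inp <- check_engine_input(expr, regulators)
  expr <- inp$expr; regulators <- inp$regulators
  if (n_bootstrap < 1L) stop("n_bootstrap must be >= 1")
  if (l1_ratio <= 0 || l1_ratio > 1) stop("l1_ratio must be in (0, 1]")
  genes <- rownames(expr)
  n <- ncol(expr)
  z <- standardize_rows(expr)
  conf <- matrix(0, nrow = length(regulators), ncol = length(genes),
                 dimnames = list(regulators, genes))
  warned <- FALSE
  for (j in seq_along(genes)) {
    tgt <- genes[j]
    feats <- setdiff(regulators, tgt)
    if (stats::sd(expr[tgt, ]) == 0) { warned <- TRUE; next }
    y <- z[tgt, ]
    x <- t(z[feats, , drop = FALSE])
    counts <- with_seed(seed + j, {
      cnt <- numeric(length(feats))
      if (length(feats) >= 2L) {
        lam <- select_lambda_bic(x, y, l1_ratio)
        lam_path <- lam * c(8, 4, 2, 1)
        for (b in seq_len(n_bootstrap)) {
          idx <- sample.int(n, n, replace = TRUE)
          fit <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx],
                                alpha = l1_ratio, lambda = lam_path,
                                standardize = FALSE, intercept = FALSE)
          beta <- as.numeric(stats::coef(fit, s = lam))[-1L]
          cnt <- cnt + (beta != 0)
        }
      } else {
        # single candidate: the KKT condition of the elastic net decides
        # selection directly (nonzero iff |x'y|/n exceeds lambda * l1_ratio)
        lam <- abs(sum(x[, 1L] * y)) / n / 2
        for (b in seq_len(n_bootstrap)) {
          idx <- sample.int(n, n, replace = TRUE)
          cnt <- cnt + (abs(sum(x[idx, 1L] * y[idx])) / n > lam * l1_ratio)
        }
      }
      cnt
    })
    conf[feats, j] <- counts / n_bootstrap
  }
  if (warned) warning("constant target profile(s): selection frequencies set to 0")
  edges_from_matrix(conf, regulators, genes, "elasticnet")
}

# Entry order of variables along the lasso path: the index of the first
# lambda at which each coefficient is nonzero, ordered (ties broken by larger
# final absolute coefficient, then column order). Variables never entering
# get position Inf.
lasso_entry_positions <- function(x, y) {
  p <- ncol(x)
  if (p == 1L) {
    return(if (abs(sum(x[, 1L] * y)) > 0) 1 else Inf)
  }
  fit <- glmnet::glmnet(x, y, alpha = 1, standardize = FALSE,
                        intercept = FALSE, nlambda = 50L)
  beta <- as.matrix(fit$beta)          # p x nlambda
  first_nz <- apply(beta != 0, 1L, function(r) {
    w <- which(r); if (length(w)) w[1L] else Inf
  })
  final_abs <- abs(beta[, ncol(beta)])
  pos <- rep(Inf, p)
  entered <- is.finite(first_nz)
  if (any(entered)) {
    ord <- order(first_nz[entered], -final_abs[entered])
    pos[which(entered)[ord]] <- seq_len(sum(entered))
  }
  pos
}

#' Stability-selection network (TIGRESS-style)
#'
#' Stability selection over a randomised least-angle-style forward selection:
#' on each of `n_resample` half-sample resamples, the regulator profiles are
#' reweighted by independent uniform weights on `[perturbation_alpha, 1]` and
#' the order in which regulators enter the lasso path is recorded for
#' `lars_steps` steps. The edge confidence is the area score
#' `mean over s = 1..lars_steps of freq(regulator entered within first s steps)`,
#' which lies in `[0, 1]`.
#'
#' @inheritParams genie3_network
#' @param n_resample Number of resamples; must be even and >= 2 (paired
#'   half-sample splits).
#' @param lars_steps Number of forward-selection steps scored; must be smaller
#'   than the number of regulators.
#' @param perturbation_alpha Lower bound of the uniform reweighting in `(0, 1]`.
#' @export
tigress_network <- function(expr, regulators, n_resample = 1000L,
                            lars_steps = 5L, perturbation_alpha = 0.2,
                            seed = 1L) {
  inp <- check_engine_input(expr, regulators)
  expr <- inp$expr; regulators <- inp$regulators
  if (n_resample < 2L || n_resample %% 2L != 0L)
    stop("n_resample must be even and >= 2")
  if (lars_steps >= length(regulators))
    stop("lars_steps must be smaller than the number of regulators")
  if (perturbation_alpha <= 0 || perturbation_alpha > 1)
    stop("perturbation_alpha must be in (0, 1]")
  genes <- rownames(expr)
  n <- ncol(expr)
  half <- floor(n / 2)
  if (half < 2L) stop("need at least 4 samples for half-sample resampling")
  z <- standardize_rows(expr)
  conf <- matrix(0, nrow = length(regulators), ncol = length(genes),
                 dimnames = list(regulators, genes))
  for (j in seq_along(genes)) {
    tgt <- genes[j]
    feats <- setdiff(regulators, tgt)
    p <- length(feats)
    if (stats::sd(expr[tgt, ]) == 0) next
    steps <- min(lars_steps, p)
    y_all <- z[tgt, ]
    x_all <- t(z[feats, , drop = FALSE])
    sel_within <- matrix(0, nrow = p, ncol = steps)  # counts
    with_seed(seed + j, {
      for (i in seq_len(n_resample / 2L)) {
        perm <- sample.int(n)
        for (idx in list(perm[seq_len(half)], perm[(half + 1L):(2L * half)])) {
          w <- stats::runif(p, perturbation_alpha, 1)
          xs <- sweep(x_all[idx, , drop = FALSE], 2L, w, `*`)
          pos <- lasso_entry_positions(xs, y_all[idx])
          for (s in seq_len(steps))
            sel_within[, s] <- sel_within[, s] + (pos <= s)
        }
      }
    })
    freq <- sel_within / n_resample
    conf[feats, j] <- rowSums(freq) / lars_steps
  }
  edges_from_matrix(conf, regulators, genes, "tigress")
}

#' Bundled inference engines
#'
#' @return Named list mapping engine name to the engine function; each takes
#'   `(expr, regulators, ...)` and returns a `ranked_edges` data.frame.
#' @export
grn_engines <- function() {
  list(pcc = pcc_network, clr = clr_network, aracne = aracne_network,
       genie3 = genie3_network, elasticnet = elasticnet_network,
       tigress = tigress_network)
}

#' Run a set of inference engines
#'
#' @inheritParams pcc_network
#' @param methods Character vector of engine names (see [grn_engines()]).
#' @param seed Global seed; each stochastic engine gets a fixed per-engine
#'   offset so adding an engine never shifts another engine's stream.
#' @param config Named list overriding engine parameters (`bins`,
#'   `dpi_tolerance`, `n_trees`, `feature_fraction`, `n_bootstrap`,
#'   `l1_ratio`, `n_resample`, `lars_steps`, `perturbation_alpha`).
#' @return Named list of `ranked_edges`.
#' @export
run_engines <- function(expr, regulators, methods, seed = 1L, config = list()) {
  engines <- grn_engines()
  unknown <- setdiff(methods, names(engines))
  if (length(unknown)) stop("unknown engine(s): ", paste(unknown, collapse = ", "))
  cfg <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  offsets <- c(pcc = 0L, clr = 0L, aracne = 0L, genie3 = 10000L,
               elasticnet = 20000L, tigress = 30000L)
  out <- lapply(methods, function(m) {
    switch(m,
      pcc = pcc_network(expr, regulators),
      clr = clr_network(expr, regulators, bins = cfg("bins", 10L)),
      aracne = aracne_network(expr, regulators, bins = cfg("bins", 10L),
                              dpi_tolerance = cfg("dpi_tolerance", 0)),
      genie3 = genie3_network(expr, regulators,
                              n_trees = cfg("n_trees", 1000L),
                              feature_fraction = cfg("feature_fraction", "sqrt"),
                              seed = seed + offsets[["genie3"]]),
      elasticnet = elasticnet_network(expr, regulators,
                                      n_bootstrap = cfg("n_bootstrap", 1000L),
                                      l1_ratio = cfg("l1_ratio", 0.5),
                                      seed = seed + offsets[["elasticnet"]]),
      tigress = tigress_network(expr, regulators,
                                n_resample = cfg("n_resample", 1000L),
                                lars_steps = cfg("lars_steps", 5L),
                                perturbation_alpha = cfg("perturbation_alpha", 0.2),
                                seed = seed + offsets[["tigress"]]))
  })
  names(out) <- methods
  out
}
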