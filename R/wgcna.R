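# Weighted-correlation-network comparator for hub ranking: soft-thresholded
# correlation adjacency -> topological overlap -> average-linkage modules ->
# module eigengenes -> module-membership (kME) ranking of regulators.
# Unsigned networks (|cor|) throughout. Module detection uses a static height
# cut plus a minimum-size filter in place of the full dynamic tree cut: the
# comparator only needs representative module structure, and the static cut
# keeps the procedure transparent and parameter-light.

#' Soft-threshold adjacency matrix
#'
#' `a_ij = |cor(i, j)|^power` with unit diagonal. Zero-variance genes have
#' undefined correlations: their rows/columns are set to 0 (diagonal 1) and a
#' warning is issued.
#'
#' @param expr Genes x samples numeric matrix.
#' @param power Soft-threshold exponent (>= 1).
#' @return Symmetric genes x genes matrix with entries in `[0, 1]`.
#' @export
wgcna_adjacency <- function(expr, power = 6) {
  expr <- validate_expression(expr)
  if (power < 1) stop("power must be >= 1")
  a <- abs(suppressWarnings(stats::cor(t(expr))))^power
  if (anyNA(a)) {
    warning("zero-variance gene(s): adjacency entries set to 0")
    a[is.na(a)] <- 0
  }
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over u distinct from i and j and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. Shared-neighbourhood similarity in `[0, 1]`.
#'
#' @param a Symmetric adjacency in `[0, 1]` with unit diagonal.
#' @export
topological_overlap <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric")
  if (any(a < -1e-12) || any(a > 1 + 1e-12)) stop("adjacency entries must be in [0, 1]")
  if (max(abs(diag(a) - 1)) > 1e-12) stop("adjacency must have unit diagonal")
  k <- rowSums(a) - 1
  # sum over shared neighbours u (u != i, j): (A^2)_ij minus the u = i and
  # u = j terms, which are a_ii a_ij + a_ij a_jj = 2 a_ij on a unit diagonal
  l <- a %*% a - 2 * a
  num <- l + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  pmin(pmax(tom, 0), 1)
}

#' Module eigengene
#'
#' First principal component of the standardised member-gene submatrix,
#' scaled to unit variance, with its sign oriented so that the mean
#' correlation with the member genes is non-negative.
#'
#' @param expr Genes x samples matrix.
#' @param members Character vector of >= 2 member gene ids.
#' @return Numeric sample profile of length `ncol(expr)`.
#' @export
module_eigengene <- function(expr, members) {
  stopifnot(length(members) >= 2L)
  sub <- expr[members, , drop = FALSE]
  z <- standardize_rows(sub)
  sv <- svd(z, nu = 0, nv = 1)
  if (sv$d[1L] < 1e-12) stop("module submatrix has rank 0")
  me <- sv$v[, 1L]
  me <- me / stats::sd(me)
  cors <- suppressWarnings(apply(sub, 1L, function(g)
    if (stats::sd(g) > 0) stats::cor(g, me) else 0))
  if (mean(cors) < 0) me <- -me
  me
}

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, computes the connectivity `k_i` of each gene
#' under the soft adjacency, bins the connectivities (about 10 occupied
#' bins), and regresses `log10(frequency)` on `log10(mean k)` per bin. The
#' fit index is the regression R-squared, sign-flipped to negative when the
#' slope is positive (scale-free topology requires a decreasing tail).
#' Returns the smallest power whose fit reaches `fit_target`; if none does,
#' the power with the best fit is returned with a warning.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate exponents (default 1:12).
#' @param fit_target Required signed R-squared (default 0.8).
#' @export
pick_soft_power <- function(expr, powers = 1:12, fit_target = 0.8) {
  if (!length(powers)) stop("no candidate powers supplied")
  powers <- sort(powers)
  fits <- vapply(powers, function(p)
    scale_free_fit(wgcna_adjacency(expr, p)), numeric(1))
  ok <- which(fits >= fit_target)
  if (length(ok)) return(powers[ok[1L]])
  warning("no candidate power reached the scale-free fit target; ",
          "returning the best-fitting power")
  powers[which.max(fits)]
}

scale_free_fit <- function(a, n_bins = 10L) {
  k <- rowSums(a) - diag(a)
  if (max(k) - min(k) < 1e-12) stop("degenerate connectivity: all equal")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  freq <- tabulate(bin, n_bins)
  kmean <- vapply(seq_len(n_bins), function(b)
    if (freq[b] > 0) mean(k[bin == b]) else NA_real_, numeric(1))
  occ <- which(freq > 0 & kmean > 0)
  if (length(occ) < 3L) stop("fewer than 3 occupied connectivity bins")
  x <- log10(kmean[occ]); y <- log10(freq[occ] / length(k))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  if (slope >= 0) -r2 else r2
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut at
#' `cut_height` times the maximum merge height, removal of modules smaller
#' than `min_module_size` (their genes become unassigned, label 0), and
#' iterative merging of module pairs whose eigengenes correlate above
#' `1 - merge_threshold` (eigengenes recomputed after each merge). Final
#' labels are renumbered 1, 2, ... by decreasing module size.
#'
#' @param tom Topological overlap matrix with gene dimnames.
#' @param expr Genes x samples matrix (for eigengenes).
#' @param min_module_size Smallest retained module (>= 2).
#' @param cut_height Static cut as a fraction of the maximum merge height,
#'   in `(0, 1)`; default 0.99.
#' @param merge_threshold Eigengene-dissimilarity below which modules merge,
#'   in `(0, 1)`; default 0.25 (merge when cor > 0.75).
#' @return List of class `module_assignment`: `labels` (named integer, 0 =
#'   unassigned), `eigengenes` (list by module label), `power` is filled by
#'   [wgcna_hub_ranking()].
#' @export
detect_modules <- function(tom, expr, min_module_size = 10L,
                           cut_height = 0.99, merge_threshold = 0.25) {
  stopifnot(min_module_size >= 2L, cut_height > 0, cut_height < 1,
            merge_threshold > 0, merge_threshold < 1)
  genes <- rownames(tom)
  if (is.null(genes)) stop("TOM needs gene dimnames")
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  labels <- stats::cutree(tree, h = cut_height * max(tree$height))
  # drop undersized modules
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_module_size])
  labels[labels %in% small] <- 0L
  if (all(labels == 0L))
    stop("all genes unassigned; lower min_module_size or raise cut_height")
  labels <- renumber_modules(labels)
  mes <- compute_eigengenes(expr, labels)
  # merge modules with similar expression until stable
  repeat {
    ids <- sort(unique(labels[labels > 0L]))
    if (length(ids) < 2L) break
    best <- NULL; best_cor <- 1 - merge_threshold
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        cc <- stats::cor(mes[[as.character(ids[i])]], mes[[as.character(ids[j])]])
        if (cc > best_cor) { best_cor <- cc; best <- c(ids[i], ids[j]) }
      }
    }
    if (is.null(best)) break
    labels[labels == best[2L]] <- best[1L]
    labels <- renumber_modules(labels)
    mes <- compute_eigengenes(expr, labels)
  }
  structure(list(labels = labels, eigengenes = mes), class = "module_assignment")
}

renumber_modules <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) return(labels)
  sizes <- vapply(ids, function(m) sum(labels == m), 0L)
  # decreasing size, ties by old label for determinism
  new_order <- ids[order(-sizes, ids)]
  out <- labels
  for (i in seq_along(new_order)) out[labels == new_order[i]] <- i
  out
}

compute_eigengenes <- function(expr, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  mes <- lapply(ids, function(m)
    module_eigengene(expr, names(labels)[labels == m]))
  names(mes) <- as.character(ids)
  mes
}

#' Rank regulators by module membership (kME)
#'
#' Each regulator's score is the absolute correlation of its expression
#' profile with its own module's eigengene; regulators left unassigned by
#' module detection fall back to their maximum `|kME|` over all module
#' eigengenes so that every regulator is rankable. Ranking is by descending
#' score, ties broken by id.
#'
#' @param expr Genes x samples matrix.
#' @param modules A `module_assignment` from [detect_modules()].
#' @param regulators Regulator universe.
#' @return Named numeric vector of kME scores in ranking order.
#' @export
kme_hub_ranking <- function(expr, modules, regulators) {
  stopifnot(inherits(modules, "module_assignment"))
  if (!length(modules$eigengenes)) stop("no modules available")
  regulators <- as.character(regulators)
  scores <- vapply(regulators, function(r) {
    prof <- expr[r, ]
    if (stats::sd(prof) == 0) return(0)
    lab <- modules$labels[[r]]
    if (!is.null(lab) && !is.na(lab) && lab > 0L) {
      abs(stats::cor(prof, modules$eigengenes[[as.character(lab)]]))
    } else {
      max(vapply(modules$eigengenes, function(me)
        abs(stats::cor(prof, me)), numeric(1)))
    }
  }, numeric(1))
  scores[rank_hubs(scores)]
}

#' WGCNA-style hub ranking (end to end)
#'
#' Runs the full comparator pipeline: soft-power selection (unless `power`
#' is given), adjacency, topological overlap, module detection, eigengenes
#' and kME ranking of the regulators.
#'
#' @inheritParams detect_modules
#' @param expr Genes x samples matrix.
#' @param regulators Regulator universe.
#' @param power Soft-threshold exponent, or `NULL` to pick it by scale-free
#'   fit.
#' @return Object of class `wgcna_hubs` with `scores` (ranked kME vector),
#'   `ranking`, `modules`, `power`.
#' @export
wgcna_hub_ranking <- function(expr, regulators, power = NULL,
                              min_module_size = 10L, cut_height = 0.99,
                              merge_threshold = 0.25) {
  expr <- validate_expression(expr)
  regulators <- unique(as.character(regulators))
  missing <- setdiff(regulators, rownames(expr))
  if (length(missing)) stop("regulator(s) not in expression matrix: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  if (is.null(power)) power <- pick_soft_power(expr)
  a <- wgcna_adjacency(expr, power)
  tom <- topological_overlap(a)
  modules <- detect_modules(tom, expr, min_module_size = min_module_size,
                            cut_height = cut_height,
                            merge_threshold = merge_threshold)
  scores <- kme_hub_ranking(expr, modules, regulators)
  structure(list(scores = scores, ranking = names(scores),
                 modules = modules, power = power),
            class = "wgcna_hubs")
}

#' @export
print.wgcna_hubs <- function(x, ...) {
  n_mod <- length(x$modules$eigengenes)
  cat(sprintf("WGCNA-style hub ranking (power %s, %d module%s)\n",
              x$power, n_mod, if (n_mod == 1L) "" else "s"))
  top <- utils::head(x$ranking, 5L)
  for (r in top) cat(sprintf("  %s  kME %.3f\n", r, x$scores[[r]]))
  invisible(x)
}

#' @export
coef.wgcna_hubs <- function(object, ...) object$scores
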