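# The consensus core: regulator outdegrees at an edge threshold, threshold
# selection by inter-method agreement, outdegree averaging into the community
# hub score, and the edge-rank-averaging consensus network comparator.

#' Regulator outdegrees among the top-T edges
#'
#' Counts, for each candidate regulator, how many of the first
#' `min(T, nrow(edges))` edges it is the source of. Ties in confidence at the
#' cut boundary are resolved by the stored list order (stable by
#' construction). Every regulator appears in the result; regulators absent
#' from the prediction count 0.
#'
#' @param edges A `ranked_edges` data.frame.
#' @param threshold Non-negative integer T, the number of top edges retained.
#' @param regulators Character vector of the regulator universe; every edge
#'   source must belong to it.
#' @return Named integer vector over `regulators` with attributes `threshold`
#'   and `method`.
#' @export
compute_outdegree <- function(edges, threshold, regulators) {
  stopifnot(inherits(edges, "ranked_edges"), threshold >= 0)
  regulators <- as.character(regulators)
  bad <- setdiff(unique(edges$regulator), regulators)
  if (length(bad)) stop("edge source(s) outside the regulator set: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  top <- edges$regulator[seq_len(min(threshold, nrow(edges)))]
  counts <- integer(length(regulators))
  names(counts) <- regulators
  tab <- table(top)
  counts[names(tab)] <- as.integer(tab)
  attr(counts, "threshold") <- as.integer(threshold)
  attr(counts, "method") <- attr(edges, "method")
  counts
}

#' Mean pairwise correlation of outdegree vectors
#'
#' The inter-method agreement statistic: the Pearson correlation over the
#' shared regulator index for every unordered pair of outdegree vectors,
#' averaged over pairs. Pairs in which either vector is constant are excluded
#' (a constant vector carries no ranking information); if every pair is
#' excluded, the similarity is undefined and `NA` is returned.
#'
#' @param vectors List of >= 2 named outdegree vectors over the same
#'   regulator universe (same names, same order).
#' @return Mean pairwise Pearson correlation, or `NA_real_` if undefined.
#' @export
pairwise_similarity <- function(vectors) {
  if (length(vectors) < 2L) stop("need at least 2 outdegree vectors")
  nms <- names(vectors[[1L]])
  for (v in vectors[-1L]) {
    if (!identical(names(v), nms))
      stop("outdegree vectors must share the same regulator universe")
  }
  vals <- numeric(0)
  for (a in seq_len(length(vectors) - 1L)) {
    for (b in (a + 1L):length(vectors)) {
      va <- as.numeric(vectors[[a]]); vb <- as.numeric(vectors[[b]])
      # degenerate (constant or length-1) vectors carry no ranking signal
      if (!isTRUE(stats::sd(va) > 0) || !isTRUE(stats::sd(vb) > 0)) next
      vals <- c(vals, stats::cor(va, vb))
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Select the edge-inclusion threshold by inter-method agreement
#'
#' Scans candidate thresholds and, at each, computes the mean pairwise
#' correlation of the predictions' regulator-outdegree vectors; the selected
#' threshold maximises this agreement, with ties (to within 1e-12, so
#' floating-point jitter cannot break them) resolved towards the smallest
#' threshold — the sparser network. Thresholds where the similarity is
#' undefined are skipped.
#'
#' @param predictions List of >= 2 `ranked_edges` data.frames.
#' @param regulators Regulator universe (character vector).
#' @param thresholds Candidate thresholds; defaults to a log-spaced grid
#'   intersected with `[1, max edges]`.
#' @return List of class `threshold_scan` with elements `thresholds`,
#'   `similarity` (named numeric, `NA` where undefined) and `selected`.
#' @export
select_threshold <- function(predictions, regulators, thresholds = NULL) {
  if (length(predictions) < 2L)
    stop("community requires >= 2 method predictions")
  max_edges <- max(vapply(predictions, nrow, 0L))
  if (is.null(thresholds)) thresholds <- default_threshold_grid(max_edges)
  thresholds <- sort(unique(as.integer(thresholds)))
  if (!length(thresholds) || any(thresholds < 1L))
    stop("candidate thresholds must be positive integers")
  sim <- vapply(thresholds, function(T) {
    od <- lapply(predictions, compute_outdegree, threshold = T,
                 regulators = regulators)
    pairwise_similarity(od)
  }, numeric(1))
  names(sim) <- thresholds
  if (all(is.na(sim)))
    stop("similarity undefined at every candidate threshold ",
         "(all outdegree vectors constant)")
  # smallest threshold within numerical reach (1e-12) of the maximum, so the
  # sparsest-network tie rule is immune to floating-point jitter in cor()
  best <- max(sim, na.rm = TRUE)
  selected <- thresholds[which(!is.na(sim) & sim >= best - 1e-12)[1L]]
  structure(list(thresholds = thresholds, similarity = sim,
                 selected = selected),
            class = "threshold_scan")
}

#' Default log-spaced threshold grid
#'
#' `{100, 200, 500, 1000, 2000, 5000, 10000, 20000, 50000, 100000}`
#' intersected with `[1, max_edges]`; if the intersection is empty (very
#' small edge lists) the grid falls back to `max_edges` itself.
#'
#' @param max_edges Largest prediction size.
#' @export
default_threshold_grid <- function(max_edges) {
  grid <- c(100L, 200L, 500L, 1000L, 2000L, 5000L,
            10000L, 20000L, 50000L, 100000L)
  grid <- grid[grid <= max_edges]
  if (!length(grid)) grid <- as.integer(max_edges)
  grid
}

#' Community hub score: average outdegree across predictions
#'
#' The hub score of regulator k is the arithmetic mean over the N predictions
#' of its outdegree among each prediction's top-T edges. Regulators absent
#' from a prediction contribute 0 for that prediction.
#'
#' @param predictions List of >= 1 `ranked_edges` data.frames.
#' @param regulators Regulator universe.
#' @param threshold Positive integer edge-inclusion threshold T.
#' @return Named numeric vector of scores in `[0, T]` with attributes
#'   `threshold` and `n_methods`.
#' @export
average_outdegree <- function(predictions, regulators, threshold) {
  if (!length(predictions)) stop("need at least 1 prediction")
  stopifnot(threshold >= 1)
  od <- vapply(predictions, function(p)
    as.numeric(compute_outdegree(p, threshold, regulators)),
    numeric(length(regulators)))
  od <- matrix(od, nrow = length(regulators))
  scores <- rowMeans(od)
  names(scores) <- as.character(regulators)
  attr(scores, "threshold") <- as.integer(threshold)
  attr(scores, "n_methods") <- length(predictions)
  scores
}

#' Rank regulators by hub score
#'
#' @param scores Named numeric vector.
#' @return Character vector of regulator ids, descending score; ties broken
#'   lexicographically by id so the ranking is deterministic.
#' @export
rank_hubs <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  names(scores)[order(-as.numeric(scores), names(scores))]
}

#' Edge-rank-averaging consensus network
#'
#' The classic consensus-over-edges comparator: every edge appearing in at
#' least one prediction receives, from each method, its rank position in that
#' method's list, or `length of that list + 1` when absent; edges are then
#' ordered by ascending mean rank (confidence = negative mean rank).
#'
#' @param predictions List of >= 2 `ranked_edges` data.frames.
#' @return A `ranked_edges` data.frame named `"edge_rank_community"`.
#' @export
edge_rank_community <- function(predictions) {
  if (length(predictions) < 2L) stop("need at least 2 predictions")
  keys <- lapply(predictions, function(p) paste(p$regulator, p$target, sep = "\r"))
  all_keys <- unique(unlist(keys))
  total <- rep(0, length(all_keys))
  for (i in seq_along(predictions)) {
    pos <- match(all_keys, keys[[i]])
    pos[is.na(pos)] <- nrow(predictions[[i]]) + 1L
    total <- total + pos
  }
  mean_rank <- total / length(predictions)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  reg <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)
  # ties in mean rank break by regulator then target id (byte order), so the
  # consensus ranking is deterministic and locale-independent
  ord <- order(mean_rank, reg, tgt, method = "radix")
  ranked_edge_list(reg[ord], tgt[ord], -mean_rank[ord],
                   method = "edge_rank_community")
}

#' Fit a community hub prediction
#'
#' The main entry point: runs a compendium of GRN inference engines on the
#' expression data (or accepts predefined ranked edge lists), selects the
#' edge-inclusion threshold that maximises inter-method agreement of
#' regulator outdegrees, and scores each regulator by its average outdegree
#' across methods.
#'
#' @param expr Genes x samples numeric matrix (ignored when `networks` is
#'   given and `methods` is empty).
#' @param regulators Character vector of candidate regulators.
#' @param methods Engine names to run (see [grn_engines()]); default
#'   `c("pcc", "clr", "genie3")`.
#' @param networks Optional list of predefined `ranked_edges` data.frames
#'   used instead of (or in addition to) engine runs.
#' @param thresholds Candidate thresholds; `NULL` for the default grid.
#' @param seed Global seed fanned out to the stochastic engines.
#' @param config Engine parameter overrides (see [run_engines()]).
#' @return Object of class `hub_community` with components `scores` (named
#'   numeric hub scores), `ranking`, `scan` (`threshold_scan`), `predictions`
#'   (list of `ranked_edges`), `regulators`, `seed`.
#' @examples
#' fx <- default_fixture()
#' fit <- hub_community(fx$expr, fx$regulators, methods = c("pcc", "clr"))
#' head(coef(fit))
#' @export
hub_community <- function(expr = NULL, regulators, methods = c("pcc", "clr", "genie3"),
                          networks = NULL, thresholds = NULL, seed = 1L,
                          config = list()) {
  regulators <- unique(as.character(regulators))
  if (!length(regulators)) stop("regulator set is empty")
  predictions <- list()
  if (!is.null(networks)) {
    stopifnot(all(vapply(networks, inherits, TRUE, "ranked_edges")))
    predictions <- c(predictions, networks)
    methods_run <- character(0)
    if (!is.null(expr) && length(methods) && !missing(methods)) {
      methods_run <- methods
    }
  } else {
    methods_run <- methods
  }
  if (length(methods_run)) {
    if (is.null(expr)) stop("expression data required to run inference engines")
    predictions <- c(predictions, run_engines(expr, regulators, methods_run,
                                              seed = seed, config = config))
  }
  if (length(predictions) < 2L)
    stop("community requires >= 2 methods or predefined networks")
  nm <- vapply(predictions, function(p) attr(p, "method") %||% "unnamed", "")
  names(predictions) <- make.unique(nm)
  scan <- select_threshold(predictions, regulators, thresholds)
  scores <- average_outdegree(predictions, regulators, scan$selected)
  structure(list(scores = scores,
                 ranking = rank_hubs(scores),
                 scan = scan,
                 predictions = predictions,
                 regulators = regulators,
                 seed = seed),
            class = "hub_community")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hub_community <- function(x, ...) {
  cat("Community hub prediction\n")
  cat(sprintf("  methods: %s\n", paste(names(x$predictions), collapse = ", ")))
  cat(sprintf("  selected edge threshold: %d (mean pairwise outdegree PCC %.3f)\n",
              x$scan$selected,
              x$scan$similarity[as.character(x$scan$selected)]))
  cat(sprintf("  regulators scored: %d\n", length(x$scores)))
  top <- utils::head(x$ranking, 5L)
  cat("  top hubs:\n")
  for (r in top)
    cat(sprintf("    %s  score %.2f\n", r, x$scores[[r]]))
  invisible(x)
}

#' @export
summary.hub_community <- function(object, ...) {
  sc <- object$scan
  out <- list(
    n_methods = length(object$predictions),
    methods = names(object$predictions),
    selected_threshold = sc$selected,
    similarity = sc$similarity,
    scores = object$scores,
    ranking = object$ranking)
  class(out) <- "summary.hub_community"
  out
}

#' @export
print.summary.hub_community <- function(x, ...) {
  cat("Community hub prediction summary\n")
  cat(sprintf("  %d methods: %s\n", x$n_methods, paste(x$methods, collapse = ", ")))
  cat("  threshold scan (mean pairwise outdegree PCC):\n")
  for (i in seq_along(x$similarity)) {
    mark <- if (as.integer(names(x$similarity)[i]) == x$selected_threshold) " *" else ""
    cat(sprintf("    T = %6s  similarity = %s%s\n", names(x$similarity)[i],
                formatC(x$similarity[i], digits = 4, format = "f"), mark))
  }
  cat("  hub score distribution:\n")
  print(summary(as.numeric(x$scores)))
  invisible(x)
}

#' @export
coef.hub_community <- function(object, ...) {
  object$scores[object$ranking]
}

#' Plot the threshold-agreement scan
#'
#' @param x A `hub_community` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hub_community <- function(x, ...) {
  sc <- x$scan
  graphics::plot(sc$thresholds, sc$similarity, type = "b", log = "x",
                 xlab = "edge-inclusion threshold T (top-ranked edges)",
                 ylab = "mean pairwise outdegree correlation", ...)
  graphics::abline(v = sc$selected, lty = 2)
  invisible(x)
}
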