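# Scoring hub predictions against a gold-standard network. The evaluation
# universe is always the full regulator set, zero-outdegree regulators
# included: dropping unscored regulators would hide false hubs.

#' Regulator outdegrees in a gold standard
#'
#' Directed standards count distinct targets per regulator; undirected
#' (PPI-style) standards count all distinct partners, regulator or not, as a
#' degree proxy for regulatory outdegree. Regulators with no edges get 0.
#'
#' @param gs A `gold_standard` object.
#' @param regulators Regulator universe (character vector).
#' @return Named integer vector over `regulators`; attribute `threshold` is
#'   the number of gold edges.
#' @export
gold_outdegree <- function(gs, regulators) {
  stopifnot(inherits(gs, "gold_standard"))
  regulators <- as.character(regulators)
  counts <- integer(length(regulators))
  names(counts) <- regulators
  if (attr(gs, "directed")) {
    tab <- table(gs$regulator)
  } else {
    tab <- table(c(gs$regulator, gs$target))
  }
  hit <- intersect(names(tab), regulators)
  counts[hit] <- as.integer(tab[hit])
  attr(counts, "threshold") <- nrow(gs)
  counts
}

align_vectors <- function(predicted, gold) {
  stopifnot(is.numeric(predicted), is.numeric(gold),
            !is.null(names(predicted)), !is.null(names(gold)))
  common <- names(gold)
  if (!all(common %in% names(predicted)))
    stop("predicted scores missing regulator(s): ",
         paste(utils::head(setdiff(common, names(predicted)), 5L), collapse = ", "))
  list(p = as.numeric(predicted[common]), g = as.numeric(gold))
}

#' Pearson performance of a hub prediction
#'
#' The headline performance statistic: the Pearson correlation between the
#' predicted regulator scores and the gold-standard outdegrees, over the full
#' regulator universe (zeros included).
#'
#' @param predicted Named numeric vector of hub scores or outdegrees.
#' @param gold Named numeric vector from [gold_outdegree()].
#' @export
performance_pcc <- function(predicted, gold) {
  v <- align_vectors(predicted, gold)
  if (stats::sd(v$p) == 0) stop("predicted vector is constant; correlation undefined")
  if (stats::sd(v$g) == 0) stop("gold vector is constant; correlation undefined")
  stats::cor(v$p, v$g)
}

#' Spearman performance of a hub prediction
#'
#' Rank correlation (average ranks on ties) between predicted scores and
#' gold outdegrees — invariant to monotone rescaling of either side.
#'
#' @inheritParams performance_pcc
#' @export
performance_spearman <- function(predicted, gold) {
  v <- align_vectors(predicted, gold)
  if (stats::sd(v$p) == 0) stop("predicted vector is constant; correlation undefined")
  if (stats::sd(v$g) == 0) stop("gold vector is constant; correlation undefined")
  stats::cor(v$p, v$g, method = "spearman")
}

#' Normalised absolute error of a hub prediction
#'
#' Predicted scores (arbitrary-scale means) and gold outdegrees (counts) are
#' each normalised to sum 1, then the mean absolute difference of the two
#' degree-fraction vectors is taken. Zero iff the vectors are proportional.
#'
#' @inheritParams performance_pcc
#' @export
absolute_error <- function(predicted, gold) {
  v <- align_vectors(predicted, gold)
  if (sum(v$p) == 0) stop("predicted vector sums to 0; cannot normalise")
  if (sum(v$g) == 0) stop("gold vector sums to 0; cannot normalise")
  mean(abs(v$p / sum(v$p) - v$g / sum(v$g)))
}

#' HITS hub scores of a thresholded edge list
#'
#' Runs the hubs-and-authorities mutual reinforcement (hub <- sum of target
#' authorities; authority <- sum of source hubs) on the directed graph of the
#' top-`threshold` edges, normalising the hub vector to unit Euclidean norm
#' each iteration, until the maximum componentwise change is < 1e-10 or 1000
#' iterations. The hub vector is the principal eigenvector of A A'.
#'
#' @param edges A `ranked_edges` data.frame.
#' @param threshold Positive number of top edges to keep.
#' @return Named numeric vector of hub scores (>= 0, unit norm) over all
#'   nodes of the thresholded graph; non-source nodes score 0.
#' @export
hits_hub_scores <- function(edges, threshold) {
  stopifnot(inherits(edges, "ranked_edges"), threshold >= 1)
  top <- edges[seq_len(min(threshold, nrow(edges))), , drop = FALSE]
  if (!nrow(top)) stop("thresholded edge set is empty")
  nodes <- unique(c(top$regulator, top$target))
  si <- match(top$regulator, nodes)
  ti <- match(top$target, nodes)
  n <- length(nodes)
  h <- rep(1 / sqrt(n), n)
  for (it in seq_len(1000L)) {
    a <- numeric(n)
    for (e in seq_len(nrow(top))) a[ti[e]] <- a[ti[e]] + h[si[e]]
    na <- sqrt(sum(a^2)); if (na > 0) a <- a / na
    h_new <- numeric(n)
    for (e in seq_len(nrow(top))) h_new[si[e]] <- h_new[si[e]] + a[ti[e]]
    nh <- sqrt(sum(h_new^2)); if (nh > 0) h_new <- h_new / nh
    delta <- max(abs(h_new - h))
    h <- h_new
    if (delta < 1e-10) break
  }
  names(h) <- nodes
  h
}

#' Evaluate a hub prediction against a gold standard
#'
#' Composes [gold_outdegree()] with the Pearson, Spearman and normalised
#' absolute-error metrics into a single report.
#'
#' @param predicted Named numeric hub scores (e.g. `coef()` of a
#'   [hub_community()] fit, or any named score vector).
#' @param gs A `gold_standard` object.
#' @param regulators Regulator universe.
#' @return Object of class `hub_performance` with fields `pcc`, `scc`,
#'   `mean_absolute_error`, `n_regulators_scored`.
#' @export
evaluate_hubs <- function(predicted, gs, regulators) {
  if (inherits(predicted, "hub_community")) predicted <- predicted$scores
  if (!nrow(gs)) stop("gold standard has no edges")
  gold <- gold_outdegree(gs, regulators)
  out <- list(pcc = performance_pcc(predicted, gold),
              scc = performance_spearman(predicted, gold),
              mean_absolute_error = absolute_error(predicted, gold),
              n_regulators_scored = length(regulators))
  class(out) <- "hub_performance"
  out
}

#' @export
print.hub_performance <- function(x, ...) {
  cat(sprintf("Hub prediction performance over %d regulators\n",
              x$n_regulators_scored))
  cat(sprintf("  Pearson  (PCC): %.4f\n", x$pcc))
  cat(sprintf("  Spearman (SCC): %.4f\n", x$scc))
  cat(sprintf("  normalised absolute error: %.4f\n", x$mean_absolute_error))
  invisible(x)
}
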