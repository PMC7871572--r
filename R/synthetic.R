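# Synthetic benchmark generator: directed regulator -> target gold standards
# with planted hubs (power-law weighted regulator outdegrees) and matching
# linear-Gaussian expression data. The linear model admits exact noiseless
# checks (regulated profiles lie in the span of their regulators) while
# preserving the hub-detectability structure the consensus pipeline needs.

#' Generate a gold-standard network with planted hubs
#'
#' Regulators are put in a random order and assigned sampling weights
#' proportional to `rank^(-outdegree_exponent)`; `n_edges` distinct directed
#' (regulator, target) pairs are then drawn with the regulator sampled by
#' weight and the target uniform over the other genes. Edges between two
#' regulators are only kept in the direction of the fixed regulator order, so
#' the regulator subgraph is acyclic and expression can be simulated in one
#' topological pass.
#'
#' @param n_genes Total number of genes.
#' @param n_regulators Number of candidate regulators (first genes by id).
#' @param n_edges Number of distinct edges to draw; at most
#'   `n_regulators * (n_genes - 1)`.
#' @param outdegree_exponent Power-law exponent (> 1); larger values
#'   concentrate edges on fewer hub regulators.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List: `gold` (a `gold_standard`), `regulators` (character vector),
#'   `genes` (all gene ids), `reg_order` (topological order of regulators).
#' @export
generate_grn <- function(n_genes = 300L, n_regulators = 20L, n_edges = 600L,
                         outdegree_exponent = 2, seed = 42L) {
  stopifnot(n_regulators >= 1L, n_regulators <= n_genes,
            n_edges >= 1L, outdegree_exponent > 1)
  if (n_edges > n_regulators * (n_genes - 1L))
    stop("n_edges exceeds the number of possible regulator-target pairs")
  genes <- sprintf("G%03d", seq_len(n_genes))
  regulators <- genes[seq_len(n_regulators)]
  with_seed(seed, {
    reg_order <- sample(regulators)           # topological order, hubs first
    weights <- seq_along(reg_order)^(-outdegree_exponent)
    weights <- weights / sum(weights)
    topo_pos <- stats::setNames(seq_along(reg_order), reg_order)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    src <- character(n_edges); dst <- character(n_edges)
    got <- 0L; tries <- 0L; budget <- 200L * n_edges
    while (got < n_edges) {
      tries <- tries + 1L
      if (tries > budget) stop("edge rejection sampling exceeded retry budget")
      r <- sample(reg_order, 1L, prob = weights)
      t <- sample(genes, 1L)
      if (t == r) next
      # keep the regulator subgraph acyclic: regulator -> regulator edges
      # must follow the fixed topological order
      if (t %in% regulators && topo_pos[[t]] <= topo_pos[[r]]) next
      key <- paste(r, t, sep = "\r")
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      got <- got + 1L
      src[got] <- r; dst[got] <- t
    }
    list(gold = gold_standard(src, dst, directed = TRUE),
         regulators = regulators, genes = genes, reg_order = reg_order)
  })
}

#' Simulate expression data from a gold-standard network
#'
#' Linear-Gaussian model: source regulators (no incoming edges) get standard
#' normal profiles; every other gene's profile is the weighted sum of its
#' regulators' profiles (one weight per edge, drawn `N(0, effect_sd^2)`) plus
#' Gaussian noise with standard deviation `noise_sd`, evaluated in
#' topological order. With `noise_sd = 0` every regulated profile lies
#' exactly in the span of its regulators' profiles.
#'
#' @param grn Output of [generate_grn()] (needs `gold`, `genes`,
#'   `regulators`, `reg_order`).
#' @param n_samples Number of samples (columns).
#' @param effect_sd Standard deviation of the regulatory weights (> 0).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Integer seed.
#' @return Genes x samples numeric matrix with ids from `grn$genes`.
#' @export
simulate_expression <- function(grn, n_samples = 200L, effect_sd = 1,
                                noise_sd = 0.5, seed = 42L) {
  stopifnot(effect_sd > 0, noise_sd >= 0, n_samples >= 2L)
  gold <- grn$gold
  genes <- grn$genes
  regulators <- grn$regulators
  # topological order: regulators in reg_order first, then all other genes
  topo <- c(grn$reg_order, setdiff(genes, regulators))
  parents <- split(seq_len(nrow(gold)), gold$target)
  # cycle guard (generate_grn guarantees this; predefined inputs may not)
  pos <- stats::setNames(seq_along(topo), topo)
  if (any(pos[gold$regulator] >= pos[gold$target] &
          gold$target %in% regulators))
    stop("gold standard is cyclic on the regulator subgraph")
  with_seed(seed, {
    w <- stats::rnorm(nrow(gold), 0, effect_sd)
    expr <- matrix(0, nrow = length(genes), ncol = n_samples,
                   dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
    for (g in topo) {
      inc <- parents[[g]]
      if (is.null(inc)) {
        expr[g, ] <- if (g %in% regulators) stats::rnorm(n_samples)
                     else stats::rnorm(n_samples, 0, noise_sd)
      } else {
        prof <- stats::rnorm(n_samples, 0, noise_sd)
        for (e in inc) prof <- prof + w[e] * expr[gold$regulator[e], ]
        expr[g, ] <- prof
      }
    }
    expr
  })
}

#' Default synthetic benchmark fixture
#'
#' The standard study conditions used throughout the package's tests and
#' examples: 300 genes, 20 regulators, 600 gold edges drawn with outdegree
#' exponent 2, and 200 samples simulated with effect scale 1 and noise 0.5,
#' all under seed 42.
#'
#' @param seed Seed for both network generation and expression simulation.
#' @return List with `expr` (300 x 200 matrix), `regulators` (20 ids),
#'   `gold` (600-edge `gold_standard`), and the generating `grn` object.
#' @export
default_fixture <- function(seed = 42L) {
  grn <- generate_grn(n_genes = 300L, n_regulators = 20L, n_edges = 600L,
                      outdegree_exponent = 2, seed = seed)
  expr <- simulate_expression(grn, n_samples = 200L, effect_sd = 1,
                              noise_sd = 0.5, seed = seed + 1L)
  list(expr = expr, regulators = grn$regulators, gold = grn$gold, grn = grn)
}
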