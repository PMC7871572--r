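# Independent brute-force oracles. These deliberately use naive loop-based
# formulations (sum-of-products correlation, double-loop MI, triple-loop TOM,
# exhaustive triangle enumeration, full rescans) so they share no code path
# with the implementation they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

oracle_mi <- function(bx, by, bins) {
  n <- length(bx)
  mi <- 0
  for (a in seq_len(bins)) {
    for (b in seq_len(bins)) {
      pab <- sum(bx == a & by == b) / n
      if (pab > 0) {
        pa <- sum(bx == a) / n
        pb <- sum(by == b) / n
        mi <- mi + pab * log(pab / (pa * pb))
      }
    }
  }
  mi
}

oracle_clr_confidence <- function(mi, i, j) {
  zi <- (mi[i, j] - mean(mi[i, ])) / stats::sd(mi[i, ])
  zj <- (mi[i, j] - mean(mi[, j])) / stats::sd(mi[, j])
  zi <- max(zi, 0); zj <- max(zj, 0)
  sqrt(zi^2 + zj^2)
}

# Exhaustive DPI pruning over every gene triple in which all three MI values
# exist (at least two regulators). Returns a logical regulators x genes
# matrix: TRUE = pruned.
oracle_dpi_removed <- function(mi, tolerance) {
  regs <- rownames(mi); genes <- colnames(mi)
  removed <- matrix(FALSE, length(regs), length(genes),
                    dimnames = dimnames(mi))
  get_mi <- function(u, v) {
    if (u %in% regs) mi[u, v] else mi[v, u]
  }
  mark <- function(u, v) {
    if (u %in% regs) removed[u, v] <<- TRUE
    if (v %in% regs) removed[v, u] <<- TRUE
  }
  fac <- 1 - tolerance
  for (tri in utils::combn(genes, 3L, simplify = FALSE)) {
    n_reg <- sum(tri %in% regs)
    if (n_reg < 2L) next
    pairs <- utils::combn(tri, 2L, simplify = FALSE)
    # all three pairs need an MI value: each pair must contain a regulator
    if (!all(vapply(pairs, function(p) p[1L] %in% regs || p[2L] %in% regs, TRUE)))
      next
    vals <- vapply(pairs, function(p) get_mi(p[1L], p[2L]), numeric(1))
    for (k in 1:3) {
      if (vals[k] < fac * min(vals[-k])) mark(pairs[[k]][1L], pairs[[k]][2L])
    }
  }
  removed
}

oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { tom[i, j] <- 1; next }
      shared <- 0
      for (u in seq_len(n)) if (u != i && u != j) shared <- shared + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      tom[i, j] <- (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

oracle_outdegree <- function(edges, threshold, regulators) {
  counts <- stats::setNames(numeric(length(regulators)), regulators)
  m <- min(threshold, nrow(edges))
  for (e in seq_len(m)) {
    r <- edges$regulator[e]
    counts[r] <- counts[r] + 1
  }
  counts
}

oracle_similarity <- function(vectors) {
  vals <- c()
  for (a in seq_along(vectors)) {
    for (b in seq_along(vectors)) {
      if (a >= b) next
      va <- as.numeric(vectors[[a]]); vb <- as.numeric(vectors[[b]])
      if (length(unique(va)) == 1L || length(unique(vb)) == 1L) next
      vals <- c(vals, oracle_pearson(va, vb))
    }
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

oracle_select_threshold <- function(predictions, regulators, thresholds) {
  thresholds <- sort(unique(thresholds))
  sims <- vapply(thresholds, function(T) {
    od <- lapply(predictions, oracle_outdegree, threshold = T,
                 regulators = regulators)
    oracle_similarity(od)
  }, numeric(1))
  defined <- which(!is.na(sims))
  if (!length(defined)) return(NA_integer_)
  best <- max(sims[defined])
  # smallest threshold within 1e-12 of the maximum (documented tie rule)
  thresholds[min(defined[sims[defined] >= best - 1e-12])]
}

oracle_average_outdegree <- function(predictions, regulators, threshold) {
  total <- stats::setNames(numeric(length(regulators)), regulators)
  for (p in predictions) total <- total + oracle_outdegree(p, threshold, regulators)
  total / length(predictions)
}

oracle_edge_rank <- function(predictions) {
  keys <- unique(unlist(lapply(predictions, function(p)
    paste(p$regulator, p$target, sep = "|"))))
  mean_rank <- vapply(keys, function(k) {
    ranks <- vapply(predictions, function(p) {
      pk <- paste(p$regulator, p$target, sep = "|")
      i <- which(pk == k)
      if (length(i)) i else nrow(p) + 1L
    }, numeric(1))
    mean(ranks)
  }, numeric(1))
  parts <- strsplit(keys, "|", fixed = TRUE)
  reg <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)
  keys[order(mean_rank, reg, tgt, method = "radix")]
}

# Random small edge-list instances for the property suites.
random_edge_lists <- function(n_lists, n_regs, n_genes, max_edges,
                              method_prefix = "m") {
  regs <- paste0("R", seq_len(n_regs))
  genes <- c(regs, paste0("T", seq_len(n_genes - n_regs)))
  lapply(seq_len(n_lists), function(l) {
    reg <- rep(regs, times = length(genes))
    tgt <- rep(genes, each = length(regs))
    keep <- which(reg != tgt)
    m <- min(max_edges, length(keep))
    pick <- sample(keep, m)
    ranked_edge_list(reg[pick], tgt[pick], stats::runif(m),
                     method = paste0(method_prefix, l))
  })
}

# Small random expression fixture with gene/sample names.
random_expression <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  m
}
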