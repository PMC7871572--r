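# Shared heavy fixtures for the acceptance-style tests, computed once per
# test run. Each entry is the full consensus fit (pcc + clr + tree ensemble)
# on a synthetic benchmark, optionally with the WGCNA-style comparator.

.acc_cache <- new.env(parent = emptyenv())

acc_fixture_fit <- function(fixture_seed, engine_seed) {
  key <- sprintf("fit_%d_%d", fixture_seed, engine_seed)
  if (is.null(.acc_cache[[key]])) {
    fx <- default_fixture(seed = fixture_seed)
    fit <- hub_community(fx$expr, fx$regulators,
                         methods = c("pcc", "clr", "genie3"),
                         seed = engine_seed)
    .acc_cache[[key]] <- list(
      fx = fx,
      fit = fit,
      gold = gold_outdegree(fx$gold, fx$regulators))
  }
  .acc_cache[[key]]
}

acc_wgcna <- function(fixture_seed) {
  key <- sprintf("wgcna_%d", fixture_seed)
  if (is.null(.acc_cache[[key]])) {
    fx <- default_fixture(seed = fixture_seed)
    .acc_cache[[key]] <- wgcna_hub_ranking(fx$expr, fx$regulators)
  }
  .acc_cache[[key]]
}

# Degraded copies of a gold ranking: confidence = edge indicator plus strong
# Gaussian noise over every candidate regulator -> target pair.
degraded_gold_copies <- function(fx, n_copies, noise_sd = 2, seed = 7) {
  regs <- fx$regulators
  genes <- rownames(fx$expr)
  reg <- rep(regs, times = length(genes))
  tgt <- rep(genes, each = length(regs))
  keep <- reg != tgt
  reg <- reg[keep]; tgt <- tgt[keep]
  gold_key <- paste(fx$gold$regulator, fx$gold$target, sep = "\r")
  is_gold <- paste(reg, tgt, sep = "\r") %in% gold_key
  set.seed(seed)
  lapply(seq_len(n_copies), function(m)
    ranked_edge_list(reg, tgt,
                     as.numeric(is_gold) + stats::rnorm(length(reg), 0, noise_sd),
                     method = paste0("pseudo", m)))
}
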