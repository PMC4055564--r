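# Shared fixture builders: small random networks and evidence patterns for
# the inference-exactness batteries.

small_random_net <- function(seed, n_disc = 3L, n_cont = 3L,
                             n_states = 2L, edge_prob = 0.4) {
  random_cgbn(generator_config(
    n_discrete = n_disc, n_continuous = n_cont, n_states = n_states,
    max_parents = 3L, edge_prob = edge_prob, pheno_edge_prob = 0.6,
    seed = seed))
}

# A random partial-evidence pattern: values come from one forward-sampled
# row (so they are always consistent), a random subset of non-target nodes
# is observed (possibly none).
random_evidence <- function(net, target, seed) {
  set.seed(seed)
  row <- sample_dataset(net, 1L, seed = seed)$df
  pool <- setdiff(net$structure$nodes, target)
  k <- sample(0:length(pool), 1L)
  obs <- if (k > 0L) sample(pool, k) else character(0)
  ev <- lapply(stats::setNames(obs, obs), function(v) row[[v]][[1L]])
  ev
}

# Deterministic two-node mixed net used by several worked examples:
# uniform binary phenotype, X | pheno ~ N(-1, 1) / N(1, 1).
gaussian_naive_net <- function() {
  g <- dag(c("pheno", "X"), cbind("pheno", "X"))
  cgbn(g,
       params = list(
         pheno = list(kind = "discrete", cpt = matrix(c(0.5, 0.5), 1L)),
         X = list(kind = "continuous", cont_parents = character(0),
                  beta = matrix(c(-1, 1), 2L, 1L), sigma2 = c(1, 1))),
       kinds = c(pheno = "discrete", X = "continuous"),
       states = list(pheno = c("neg", "pos")),
       phenotype = "pheno")
}

# Star network with `n_children` strongly informative continuous children;
# used by the recovery tests (true blanket = the children).
strong_star_net <- function(seed, n_children = 4L, pheno_edge_prob = 0.7) {
  random_cgbn(generator_config(
    n_discrete = 1L, n_continuous = n_children, max_parents = 3L,
    edge_prob = 0, pheno_edge_prob = pheno_edge_prob,
    effect_range = c(2, 3), seed = seed))
}
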