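# Experiment drivers for the discretization benchmarks: how much predictive
# AUC is lost when continuous variables are binned before network learning.

#' Mixed-versus-discretized learning benchmark
#'
#' Generates `n_networks` random conditional Gaussian networks, samples a
#' small training set and an independent test set from each, and learns a
#' network per training set twice: once from the original mixed data and once
#' after equal-width discretization of every continuous column (test data are
#' binned on the training grid). Test-set AUC for phenotype prediction is
#' recorded for both arms.
#'
#' @param n_networks number of replicate networks (default 10).
#' @param n_train,n_test training and test sample sizes. The default
#'   training size of 25 probes the variables-comparable-to-samples regime;
#'   the test set is larger so the AUC estimate itself is stable.
#' @param cfg a `generator_config` describing the network family (seed field
#'   ignored; per-replicate seeds derive from `seed`).
#' @param bins number of equal-width bins for the discretized arm.
#' @param config a `search_config` used for both arms.
#' @param seed master seed; replicate `i` uses `seed + i` for the network
#'   and offset seeds for its samples.
#' @return An object of class `discretization_benchmark`: data frame
#'   `results` (per network: `auc_continuous`, `auc_discretized`), plus
#'   `mean_auc_continuous`, `mean_auc_discretized` and `mean_gap` (all in
#'   \[0, 1\]).
#' @export
discretization_benchmark <- function(n_networks = 10L, n_train = 25L,
                                     n_test = 400L,
                                     cfg = generator_config(),
                                     bins = 10L,
                                     config = search_config(),
                                     seed = 1L) {
  rows <- vector("list", n_networks)
  for (i in seq_len(n_networks)) {
    cfg_i <- cfg
    cfg_i$seed <- seed + i
    net <- random_cgbn(cfg_i)
    train <- sample_dataset(net, n_train, seed = seed + 10000L + i)
    test <- sample_dataset(net, n_test, seed = seed + 20000L + i)

    cont <- train_and_score(train, test, config)
    auc_c <- roc_auc(cont$scores, cont$labels)$auc

    dtrain <- discretize_equal_width(train, bins)
    dtest <- discretize_equal_width(test, bins,
                                    edges = attr(dtrain, "bin_edges"))
    disc <- train_and_score(dtrain, dtest, config)
    auc_d <- roc_auc(disc$scores, disc$labels)$auc

    rows[[i]] <- data.frame(network = i, auc_continuous = auc_c,
                            auc_discretized = auc_d)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 mean_auc_continuous = mean(results$auc_continuous),
                 mean_auc_discretized = mean(results$auc_discretized),
                 mean_gap = mean(results$auc_continuous -
                                 results$auc_discretized)),
            class = "discretization_benchmark")
}

#' @export
print.discretization_benchmark <- function(x, ...) {
  cat(sprintf(
    "Discretization benchmark over %d networks:\n  mean test AUC %.3f (mixed) vs %.3f (10-bin discretized), gap %.3f\n",
    nrow(x$results), x$mean_auc_continuous, x$mean_auc_discretized,
    x$mean_gap))
  invisible(x)
}

#' Discretization AUC gap on random mixed networks
#'
#' Probes the regime where the number of variables is comparable to the
#' sample size: each replicate draws a random network over `n_nodes` nodes
#' whose kinds (discrete/continuous) are chosen by a fair coin (phenotype
#' always discrete binary), samples train and test sets of `n` rows, learns
#' and evaluates once on the original data and once after equal-width
#' discretization, and records the per-network difference in test AUC.
#' Replicates in which discretization changes nothing (all-discrete networks
#' and exact AUC ties) carry no information about the cost of binning and
#' are excluded from the average, mirroring how such paired comparisons are
#' usually summarized.
#'
#' @param n_replicates number of random networks (default 10).
#' @param n_nodes total number of variables (default 25).
#' @param n training sample size (default 25, the variables-comparable-to-
#'   samples regime).
#' @param n_test held-out rows used to measure each AUC; larger than `n` so
#'   the per-replicate AUC estimate is not the noise floor.
#' @param bins number of bins.
#' @param config a `search_config`.
#' @param seed master seed.
#' @param cfg_template a `generator_config` whose effect/variance/edge
#'   settings are reused (counts and seed are overridden per replicate). The
#'   default connects the phenotype to later nodes at the same uniform rate
#'   as any other pair: unlike the case-control benchmark generator, these
#'   networks have no designed continuous signal layer, so blankets are a
#'   random mix of discrete and continuous members.
#' @return An object of class `discretization_gap`: data frame `results`
#'   (per replicate AUCs and difference) and `mean_gap`, the average
#'   continuous-minus-discretized test AUC difference over informative
#'   replicates.
#' @export
discretization_gap <- function(n_replicates = 10L, n_nodes = 25L, n = 25L,
                               n_test = 200L, bins = 10L,
                               config = search_config(), seed = 1L,
                               cfg_template = generator_config(
                                 pheno_edge_prob = 0.25)) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(seed + 500L + i)
    nd <- 1L + stats::rbinom(1L, n_nodes - 1L, 0.5)
    cfg_i <- cfg_template
    cfg_i$n_discrete <- nd
    cfg_i$n_continuous <- n_nodes - nd
    cfg_i$seed <- seed + i
    net <- random_cgbn(cfg_i)
    train <- sample_dataset(net, n, seed = seed + 30000L + i)
    test <- sample_dataset(net, n_test, seed = seed + 40000L + i)
    if (length(unique(test$df[[test$phenotype]])) < 2L ||
        length(unique(train$df[[train$phenotype]])) < 2L) {
      rows[[i]] <- data.frame(replicate = i, n_discrete = nd,
                              auc_continuous = NA_real_,
                              auc_discretized = NA_real_, gap = NA_real_)
      next
    }
    cont <- train_and_score(train, test, config)
    auc_c <- roc_auc(cont$scores, cont$labels)$auc
    dtrain <- discretize_equal_width(train, bins)
    dtest <- discretize_equal_width(test, bins,
                                    edges = attr(dtrain, "bin_edges"))
    disc <- train_and_score(dtrain, dtest, config)
    auc_d <- roc_auc(disc$scores, disc$labels)$auc
    rows[[i]] <- data.frame(replicate = i, n_discrete = nd,
                            auc_continuous = auc_c, auc_discretized = auc_d,
                            gap = auc_c - auc_d)
  }
  results <- do.call(rbind, rows)
  informative <- results$gap[!is.na(results$gap) & results$gap != 0]
  structure(list(results = results,
                 mean_gap = mean(informative)),
            class = "discretization_gap")
}

#' @export
print.discretization_gap <- function(x, ...) {
  cat(sprintf(
    "Discretization gap over %d replicates: mean test-AUC loss %.3f\n",
    nrow(x$results), x$mean_gap))
  invisible(x)
}
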