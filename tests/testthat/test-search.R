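make_noise_data <- function(seed, n = 60L, n_disc = 2L, n_cont = 3L) {
  set.seed(seed)
  df <- data.frame(ph = sample(c("a", "b"), n, TRUE))
  for (i in seq_len(n_disc))
    df[[paste0("d", i)]] <- sample(c("u", "v"), n, TRUE)
  for (i in seq_len(n_cont))
    df[[paste0("x", i)]] <- rnorm(n)
  mixed_data(df, "ph")
}

strong_signal_data <- function(seed, n = 500L) {
  set.seed(seed)
  ph <- sample(c("a", "b"), n, TRUE)
  mixed_data(data.frame(ph = ph,
                        X = rnorm(n, ifelse(ph == "a", -2, 2)),
                        z = rnorm(n)), "ph")
}

test_that("K2 ordering puts the phenotype first, independence earliest", {
  md <- make_noise_data(1)
  ord <- k2_order(md)
  expect_setequal(ord, cgbnet:::var_names(md))
  expect_identical(ord[[1L]], "ph")

  set.seed(2)
  ph <- sample(c("a", "b"), 200, TRUE)
  md2 <- mixed_data(data.frame(ph = ph, copy = ph, noise = rnorm(200)), "ph")
  ord2 <- k2_order(md2)
  expect_lt(match("noise", ord2), match("copy", ord2))
})

test_that("K2 search honors the order, parent limit and recovers signal", {
  md <- strong_signal_data(3)
  cfg0 <- search_config("k2", prior = prior_hyper(max_parents = 0))
  expect_equal(nrow(edge_matrix(learn_k2(md, config = cfg0))), 0L)

  cfg <- search_config("k2")
  ord <- k2_order(md, prior = cfg$prior)
  g <- learn_k2(md, ord, cfg)
  expect_true("ph" %in% g$parents$X)

  md2 <- make_noise_data(4)
  ord2 <- k2_order(md2)
  g2 <- learn_k2(md2, ord2, search_config("k2"))
  for (v in g2$nodes)
    for (p in g2$parents[[v]])
      expect_lt(match(p, ord2), match(v, ord2))
  expect_error(learn_k2(md2, c("ph", "ph"), search_config("k2")),
               "permutation")
})

test_that("greedy search improves monotonically and stops on no gain", {
  md <- make_noise_data(5)
  g <- learn_greedy_exhaustive(md, search_config("greedy"))
  tr <- attr(g, "score_trajectory")
  expect_true(all(diff(tr) > 0) || length(tr) == 1L)
  expect_lte(nrow(edge_matrix(g)), 1L)  # independent variables: near-empty
  expect_gte(attr(g, "score"), network_score(dag(g$nodes), md))

  md2 <- strong_signal_data(6)
  g2 <- learn_greedy_exhaustive(md2, search_config("greedy"))
  expect_true(has_edge <- "ph" %in% g2$parents$X || "X" %in% g2$parents$ph)
  # CG constraint forbids X -> ph, so the edge must be ph -> X
  expect_true("ph" %in% g2$parents$X)
})

test_that("greedy backtracking can only match or improve the score", {
  md <- strong_signal_data(7, n = 200)
  s_plain <- attr(learn_greedy_exhaustive(md, search_config("greedy")), "score")
  s_back <- attr(learn_greedy_exhaustive(
    md, search_config("greedy", backtracking = TRUE)), "score")
  expect_gte(s_back, s_plain - 1e-9)
})

test_that("pheno-centric search never gives the phenotype parents", {
  md <- make_noise_data(8)
  g <- learn_pheno_centric(md, config = search_config("pheno_centric"))
  expect_length(g$parents$ph, 0L)
  expect_equal(nrow(edge_matrix(g)), 0L)  # pure noise: no blanket

  # naive-Bayes style simulation: informative children all recovered
  set.seed(9)
  n <- 500
  ph <- sample(c("a", "b"), n, TRUE)
  df <- data.frame(ph = ph)
  for (i in 1:5)
    df[[paste0("x", i)]] <- rnorm(n, ifelse(ph == "a", -1.5, 1.5))
  md2 <- mixed_data(df, "ph")
  g2 <- learn_pheno_centric(md2, config = search_config("pheno_centric"))
  expect_setequal(markov_blanket(g2, "ph"), paste0("x", 1:5))
  # every edge touches the blanket
  em <- edge_matrix(g2)
  blanket <- c("ph", markov_blanket(g2, "ph"))
  expect_true(all(em[, 1L] %in% blanket | em[, 2L] %in% blanket))
})

test_that("simulated annealing is seed-deterministic and no worse than empty", {
  md <- strong_signal_data(10, n = 200)
  cfg <- search_config("annealing", seed = 42)
  g1 <- learn_simulated_annealing(md, cfg)
  g2 <- learn_simulated_annealing(md, cfg)
  expect_identical(edge_matrix(g1), edge_matrix(g2))
  expect_gte(attr(g1, "score"), network_score(dag(g1$nodes), md))
  expect_true("ph" %in% g1$parents$X)

  # at (near) zero temperature no worsening move is ever accepted
  g3 <- learn_simulated_annealing(md, cfg, t0 = 1e-12)
  expect_gte(attr(g3, "score"), network_score(dag(g3$nodes), md))
})

test_that("all algorithms return legal structures within the parent limit", {
  algorithms <- c("k2", "greedy", "pheno_centric", "annealing")
  for (s in 1:12) {
    md <- make_noise_data(300 + s, n = 40L, n_disc = 2L, n_cont = 3L)
    for (alg in algorithms) {
      cfg <- search_config(alg, prior = prior_hyper(max_parents = 2),
                           seed = s)
      g <- learn_network(md, cfg)
      expect_true(is_acyclic(g))
      expect_identical(validate_cg_constraints(g, md), character(0))
      expect_true(all(lengths(g$parents) <= 2L))
    }
  }
})

test_that("candidate-evaluation counts respect the complexity anchors", {
  k <- 3L
  for (s in 1:5) {
    md <- make_noise_data(400 + s, n = 50L, n_disc = 3L, n_cont = 4L)
    n <- length(cgbnet:::var_names(md))
    g_k2 <- learn_k2(md, k2_order(md), search_config("k2"))
    expect_lte(attr(g_k2, "n_evals"), (k / 2) * n^2)
    g_gr <- learn_greedy_exhaustive(md, search_config("greedy"))
    expect_lte(attr(g_gr, "max_sweep_evals"), n^2 + k * n^2)
    g_ph <- learn_pheno_centric(md, config = search_config("pheno_centric"))
    expect_lte(attr(g_ph, "n_evals"), n + k * n^2)
  }
})

test_that("naive Bayes builder stars the phenotype", {
  md <- make_noise_data(20)
  g <- naive_bayes_structure(md)
  expect_setequal(children_of <- cgbnet:::children_of(g, "ph"),
                  setdiff(cgbnet:::var_names(md), "ph"))
  expect_length(g$parents$ph, 0L)
})
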