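test_that("BDeu score reproduces hand-derived sequential predictives", {
  md <- mixed_data(data.frame(y = c("1", "1", "2")), "y")
  expect_equal(bdeu_family_score(md, "y", prior = prior_hyper(alpha = 2)),
               log(1 / 12), tolerance = 1e-12)
  # first predictive observation is uniform regardless of alpha
  one <- mixed_data(data.frame(y = "1", stringsAsFactors = FALSE), "y",
                    states = list(y = c("1", "2", "3")))
  for (a in c(0.5, 1, 7))
    expect_equal(bdeu_family_score(one, "y", prior = prior_hyper(alpha = a)),
                 log(1 / 3), tolerance = 1e-12)
  md2 <- mixed_data(data.frame(y = c("1", "2", "1", "2"),
                               p = c("1", "1", "2", "2")), "p")
  expect_equal(bdeu_family_score(md2, "y", "p", prior_hyper(alpha = 4)),
               log(1 / 36), tolerance = 1e-12)
})

test_that("BDeu equals the sequential-predictive oracle on a small grid", {
  set.seed(11)
  for (r in 2:3) for (qp in list(character(0), "p1", c("p1", "p2"))) {
    for (alpha in c(0.5, 1, 2, 4)) {
      for (n in c(1L, 3L, 6L)) {
        child <- sample(r, n, replace = TRUE)
        df <- data.frame(y = paste0("k", child))
        states <- list(y = paste0("k", 1:r))
        q <- 1L
        for (p in qp) {
          df[[p]] <- paste0("s", sample(2, n, replace = TRUE))
          states[[p]] <- c("s1", "s2")
          q <- q * 2L
        }
        df$ph <- rep("a", n)
        md <- mixed_data(df, "ph", states = states)
        pidx <- rep(1L, n)
        for (p in qp) pidx <- (pidx - 1L) * 2L + match(df[[p]], c("s1", "s2"))
        expect_equal(
          bdeu_family_score(md, "y", qp, prior_hyper(alpha = alpha)),
          bdeu_seq_oracle(child, pidx, r, q, alpha),
          tolerance = 1e-10)
      }
    }
  }
})

test_that("exp(BDeu score) is a probability over the dataset space", {
  for (n in 1:3) for (alpha in c(0.7, 1, 3)) {
    total <- 0
    for (cfg in 0:(2^n - 1)) {
      states <- ifelse(bitwAnd(cfg, 2^(seq_len(n) - 1)) > 0, "b", "a")
      md <- mixed_data(data.frame(y = states), "y",
                       states = list(y = c("a", "b")))
      total <- total + exp(bdeu_family_score(md, "y",
                                             prior = prior_hyper(alpha = alpha)))
    }
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("CLG score is exchangeable and matches quadrature", {
  set.seed(21)
  y <- rnorm(8, 1, 2)
  x <- rnorm(8)
  md <- mixed_data(data.frame(ph = rep(c("a", "b"), 4), y = y, x = x), "ph")
  s <- clg_family_score(md, "y")
  perm <- sample(8)
  expect_equal(clg_family_score(subset_rows(md, perm), "y"), s,
               tolerance = 1e-12)
  # no parents: 2-D quadrature oracle
  expect_equal(s, nig_quad_oracle_0p(y), tolerance = 1e-4 * abs(s))
  sm <- clg_family_score(subset_rows(md, 1:5), "y",
                         prior = prior_hyper(nu = 2, sigma0_sq = 0.5))
  expect_equal(sm, nig_quad_oracle_0p(y[1:5], nu = 2, sigma0_sq = 0.5),
               tolerance = 1e-4 * abs(sm))
  # one continuous parent: 3-D quadrature oracle
  s1 <- clg_family_score(md, "y", cont_parents = "x")
  expect_equal(s1, nig_quad_oracle_1p(y, x), tolerance = 1e-4 * abs(s1))
})

test_that("CLG score prefers the true regression parent", {
  set.seed(31)
  x <- rnorm(50)
  y <- 2 * x + rnorm(50, sd = 0.1)
  md <- mixed_data(data.frame(ph = rep(c("a", "b"), 25), x = x, y = y), "ph")
  expect_gt(clg_family_score(md, "y", cont_parents = "x"),
            clg_family_score(md, "y"))
})

test_that("discrete-parent strata with no rows contribute nothing", {
  md <- mixed_data(data.frame(ph = c("a", "a", "a"), y = c(1.2, -0.5, 0.3)),
                   "ph", states = list(ph = c("a", "b")))
  expect_equal(clg_family_score(md, "y", disc_parents = "ph"),
               clg_family_score(md, "y"), tolerance = 1e-12)
})

test_that("network score decomposes over families", {
  net <- small_random_net(3)
  md <- sample_dataset(net, 60, seed = 4)
  prior <- prior_hyper()
  empty <- dag(net$structure$nodes)
  s_empty <- network_score(empty, md, prior)
  expect_equal(s_empty,
               sum(vapply(net$structure$nodes, function(v)
                 cgbnet:::family_score(md, v, character(0), prior),
                 numeric(1))),
               tolerance = 1e-12)
  # swapping one family's parent set moves the total by that family's delta
  g1 <- add_edge(empty, "pheno", "X1")
  delta <- cgbnet:::family_score(md, "X1", "pheno", prior) -
    cgbnet:::family_score(md, "X1", character(0), prior)
  expect_equal(network_score(g1, md, prior) - s_empty, delta,
               tolerance = 1e-12)
  expect_error(network_score(dag(net$structure$nodes, cbind("X1", "pheno")),
                             md, prior), "illegal CG")
})

test_that("spurious edges usually lower the score, real ones raise it", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    md <- mixed_data(data.frame(ph = sample(c("a", "b"), 500, TRUE),
                                u = rnorm(500), v = rnorm(500)), "ph")
    g0 <- dag(c("ph", "u", "v"))
    if (network_score(add_edge(g0, "u", "v"), md) < network_score(g0, md))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)

  net <- strong_star_net(7, pheno_edge_prob = 1)
  md <- sample_dataset(net, 1000, seed = 8)
  expect_gte(network_score(net$structure, md),
             network_score(dag(net$structure$nodes), md))
})

test_that("Bayes-factor filter ranks phenotype copies above noise", {
  set.seed(51)
  ph <- sample(c("a", "b"), 100, TRUE)
  md <- mixed_data(data.frame(ph = ph, copy = ph,
                              n1 = sample(c("x", "y"), 100, TRUE),
                              n2 = rnorm(100)), "ph")
  out <- bayes_factor_filter(md)
  expect_identical(out$variable[1L], "copy")
  expect_gt(out$log_bf[1L], 0)

  # statistically identical candidate is filtered out at threshold 0
  set.seed(52)
  md2 <- mixed_data(data.frame(ph = sample(c("a", "b"), 1000, TRUE),
                               flat = rnorm(1000)), "ph")
  expect_equal(nrow(bayes_factor_filter(md2)), 0L)

  expect_equal(nrow(bayes_factor_filter(md, candidates = character(0))), 0L)
  expect_error(bayes_factor_filter(md, candidates = c("ph", "n1")),
               "candidate")
})
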