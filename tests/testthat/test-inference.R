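test_that("posterior-mean parameter fitting matches closed forms", {
  md <- mixed_data(data.frame(y = c("1", "1", "1", "2")), "y")
  net <- fit_parameters(dag("y"), md, prior_hyper(alpha = 2))
  expect_equal(as.numeric(net$params$y$cpt), c(4 / 6, 2 / 6), tolerance = 1e-12)

  # consistency of the conditional Gaussian fit on a large sample
  set.seed(61)
  n <- 5000
  md2 <- mixed_data(data.frame(ph = sample(c("a", "b"), n, TRUE),
                               x = rnorm(n, 5, 2)), "ph")
  net2 <- fit_parameters(dag(c("ph", "x")), md2)
  se_mean <- 2 / sqrt(n)
  expect_lt(abs(net2$params$x$beta[1, 1] - 5), 3 * se_mean)
  expect_lt(abs(net2$params$x$sigma2[1] - 4), 3 * 4 * sqrt(2 / n))

  # empty configuration falls back to prior means
  md3 <- mixed_data(data.frame(ph = rep("a", 4), x = rnorm(4),
                               d = c("u", "u", "v", "v")), "ph",
                    states = list(ph = c("a", "b"), d = c("u", "v")))
  g3 <- dag(c("ph", "x", "d"), cbind(c("ph", "ph"), c("x", "d")))
  net3 <- fit_parameters(g3, md3, prior_hyper(sigma0_sq = 2.5))
  expect_equal(as.numeric(net3$params$d$cpt[2L, ]), c(0.5, 0.5))
  expect_equal(unname(net3$params$x$beta[2L, 1L]), 0)
  expect_equal(net3$params$x$sigma2[2L], 2.5)
})

test_that("joint log density factorizes correctly", {
  one <- cgbn(dag("d"), list(d = list(kind = "discrete",
                                      cpt = matrix(c(0.25, 0.75), 1L))),
              c(d = "discrete"), list(d = c("1", "2")), "d")
  expect_equal(joint_log_density(one, list(d = "2")), log(0.75))

  g <- dag(c("ph", "z"), NULL)
  std <- cgbn(g, list(ph = list(kind = "discrete",
                                cpt = matrix(c(0.5, 0.5), 1L)),
                      z = list(kind = "continuous",
                               cont_parents = character(0),
                               beta = matrix(0, 1L, 1L), sigma2 = 1)),
              c(ph = "discrete", z = "continuous"),
              list(ph = c("a", "b")), "ph")
  expect_equal(joint_log_density(std, list(ph = "a", z = 0)),
               log(0.5) - 0.5 * log(2 * pi))
  expect_error(joint_log_density(std, list(ph = "a")), "missing node")
})

test_that("exp(joint density) integrates to one by Monte Carlo", {
  # forward samples scored under the model: E[1] with importance weight 1,
  # so the average joint density of samples equals the self-normalized check
  net <- small_random_net(77, n_disc = 2, n_cont = 2)
  md <- sample_dataset(net, 2000, seed = 78)
  ll <- numeric(200)
  for (i in 1:200)
    ll[i] <- joint_log_density(net, as.list(md$df[i, , drop = FALSE]))
  expect_true(all(is.finite(ll)))
  # cross-check the vectorized per-row density used by prediction
  tot <- 0
  for (v in net$structure$nodes)
    tot <- tot + cgbnet:::row_family_loglik(net, md, v)
  expect_equal(tot[1:200], ll, tolerance = 1e-10)
})

test_that("posterior prediction reproduces hand-computed Bayes rules", {
  net <- gaussian_naive_net()
  expect_equal(unname(predict_posterior(net, list(X = 0), "pheno")),
               c(0.5, 0.5), tolerance = 1e-12)
  post <- predict_posterior(net, list(X = 1), "pheno")
  expect_equal(unname(post[["pos"]]), exp(2) / (1 + exp(2)), tolerance = 1e-9)
  expect_equal(unname(post[["pos"]]), 0.88080, tolerance = 5e-6)

  g2 <- dag(c("ph", "D"), cbind("ph", "D"))
  net2 <- cgbn(g2, list(ph = list(kind = "discrete",
                                  cpt = matrix(c(0.5, 0.5), 1L)),
                        D = list(kind = "discrete",
                                 cpt = matrix(c(0.9, 0.1, 0.2, 0.8), 2L,
                                              byrow = TRUE))),
               c(ph = "discrete", D = "discrete"),
               list(ph = c("pos", "neg"), D = c("1", "2")), "ph")
  expect_equal(unname(predict_posterior(net2, list(D = "1"), "ph")),
               c(9 / 11, 2 / 11), tolerance = 1e-12)
})

test_that("prediction equals the dense enumeration oracle", {
  # a focused battery here; the full 50-net sweep runs in the acceptance suite
  for (s in 1:6) {
    net <- small_random_net(200 + s, n_disc = 3, n_cont = 3)
    for (e in 1:4) {
      ev <- random_evidence(net, "pheno", 1000 * s + e)
      expect_equal(predict_posterior(net, ev, "pheno"),
                   oracle_predict(net, ev, "pheno"), tolerance = 1e-10)
    }
  }
})

test_that("prediction matches empirical conditional frequencies", {
  net <- small_random_net(91, n_disc = 3, n_cont = 1, edge_prob = 0.6)
  md <- sample_dataset(net, 1e6, seed = 92)
  ev <- list(D1 = net$states$D1[[1L]], D2 = net$states$D2[[2L]])
  rows <- md$df$D1 == ev$D1 & md$df$D2 == ev$D2
  emp <- mean(md$df$pheno[rows] == "case")
  post <- predict_posterior(net, ev, "pheno")[["case"]]
  se <- sqrt(post * (1 - post) / sum(rows))
  expect_lt(abs(emp - post), 3 * se + 1e-12)
})

test_that("markov-blanket evidence is sufficient for dataset prediction", {
  net <- small_random_net(44, n_disc = 3, n_cont = 3)
  md <- sample_dataset(net, 50, seed = 45)
  pred <- predict_dataset(net, md)
  expect_equal(rowSums(pred$posterior), rep(1, 50), tolerance = 1e-9)

  # agrees with full-evidence exact enumeration row by row
  for (i in c(1L, 7L, 23L)) {
    ev <- as.list(md$df[i, setdiff(names(md$df), "pheno"), drop = FALSE])
    expect_equal(unname(pred$posterior[i, ]),
                 unname(predict_posterior(net, ev, "pheno")),
                 tolerance = 1e-10)
  }

  # perturbing a variable outside the blanket leaves the posterior unchanged
  mb <- markov_blanket(net$structure, "pheno")
  outside <- setdiff(net$structure$nodes, c("pheno", mb))
  if (length(outside)) {
    md2 <- md
    v <- outside[[1L]]
    if (net$kinds[[v]] == "continuous") {
      md2$df[[v]] <- md2$df[[v]] + 100
    } else {
      st <- net$states[[v]]
      md2$df[[v]] <- st[(match(md2$df[[v]], st) %% length(st)) + 1L]
    }
    expect_equal(predict_dataset(net, md2)$posterior, pred$posterior,
                 tolerance = 1e-12)
  }

  # identical rows yield identical posteriors
  md3 <- subset_rows(md, rep(1L, 5L))
  p3 <- predict_dataset(net, md3)$posterior
  expect_equal(p3, p3[rep(1L, 5L), , drop = FALSE], tolerance = 0)
})

test_that("predictions from the generating network separate the classes", {
  net <- strong_star_net(55, pheno_edge_prob = 1)
  md <- sample_dataset(net, 200, seed = 56)
  pred <- predict_dataset(net, md)
  truth <- md$df$pheno
  mean_true <- mean(pred$posterior[cbind(seq_len(200), match(truth, colnames(pred$posterior)))])
  expect_gt(mean_true, 0.5)
})

test_that("prediction guards reject malformed queries", {
  net <- gaussian_naive_net()
  expect_error(predict_posterior(net, list(pheno = "pos", X = 1), "pheno"),
               "must not appear")
  expect_error(predict_posterior(net, list(X = 1), "X"), "must be discrete")
  expect_error(predict_posterior(net, list(Q = 1), "pheno"), "unknown node")

  expect_error(predict_dataset(net, mixed_data(data.frame(z = 1), "z",
                                               kinds = c(z = "discrete"))),
               "Markov-blanket column 'X'")

  # unseen discrete state in prediction data is rejected by name
  g <- dag(c("ph", "D"), cbind("ph", "D"))
  net2 <- cgbn(g, list(ph = list(kind = "discrete", cpt = matrix(c(.5, .5), 1L)),
                       D = list(kind = "discrete",
                                cpt = matrix(c(.7, .3, .4, .6), 2L, byrow = TRUE))),
               c(ph = "discrete", D = "discrete"),
               list(ph = c("a", "b"), D = c("u", "v")), "ph")
  bad <- mixed_data(data.frame(ph = "a", D = "w"), "ph",
                    states = list(ph = c("a", "b"), D = "w"))
  expect_error(predict_dataset(net2, bad), "outside declared states")

  # user-supplied zero CPTs can make evidence impossible
  net3 <- cgbn(g, list(ph = list(kind = "discrete", cpt = matrix(c(.5, .5), 1L)),
                       D = list(kind = "discrete",
                                cpt = matrix(c(1, 0, 1, 0), 2L, byrow = TRUE))),
               c(ph = "discrete", D = "discrete"),
               list(ph = c("a", "b"), D = c("u", "v")), "ph")
  expect_error(predict_posterior(net3, list(D = "v"), "ph"),
               "degenerate evidence")
})
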