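# Independent oracles used by the test suite. These deliberately avoid the
# package's computational paths: the discrete score oracle multiplies
# sequential predictive probabilities, the continuous score oracle integrates
# the prior numerically, and the prediction oracle enumerates the full
# discrete configuration space with textbook multivariate normal formulas
# (explicit matrix inversion, no topological recursion).

# Dirichlet-multinomial marginal likelihood by the chain rule of sequential
# predictive probabilities, stratified by parent configuration.
bdeu_seq_oracle <- function(child_idx, parent_idx, r, q, alpha) {
  logp <- 0
  for (j in seq_len(q)) {
    xs <- child_idx[parent_idx == j]
    counts <- rep(0, r)
    for (t in seq_along(xs)) {
      k <- xs[[t]]
      logp <- logp + log((alpha / (r * q) + counts[[k]]) /
                           (alpha / q + t - 1))
      counts[[k]] <- counts[[k]] + 1
    }
  }
  logp
}

dinvgamma <- function(x, shape, rate) {
  rate^shape / gamma(shape) * x^(-shape - 1) * exp(-rate / x)
}

# 2-D quadrature of the parentless Gaussian marginal likelihood:
# integral over sigma^2 and mu of prod N(y | mu, s2) N(mu | 0, s2/nu) IG(s2).
nig_quad_oracle_0p <- function(y, nu = 1, sigma0_sq = 1) {
  inner <- function(s2) {
    vapply(s2, function(s) {
      f <- function(mu)
        vapply(mu, function(m)
          prod(stats::dnorm(y, m, sqrt(s))) *
            stats::dnorm(m, 0, sqrt(s / nu)), numeric(1))
      stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value *
        dinvgamma(s, nu / 2, nu * sigma0_sq / 2)
    }, numeric(1))
  }
  log(stats::integrate(inner, 0, Inf, rel.tol = 1e-8)$value)
}

# 3-D quadrature with one continuous parent: coefficients (b0, b1) and s2.
nig_quad_oracle_1p <- function(y, x, nu = 1, sigma0_sq = 1) {
  f_s2 <- function(s2) {
    vapply(s2, function(s) {
      sd_b <- sqrt(s / nu)
      f_b0 <- function(b0)
        vapply(b0, function(a) {
          f_b1 <- function(b1)
            vapply(b1, function(b)
              prod(stats::dnorm(y, a + b * x, sqrt(s))) *
                stats::dnorm(b, 0, sd_b), numeric(1))
          stats::integrate(f_b1, -Inf, Inf, rel.tol = 1e-10)$value *
            stats::dnorm(a, 0, sd_b)
        }, numeric(1))
      stats::integrate(f_b0, -Inf, Inf, rel.tol = 1e-9)$value *
        dinvgamma(s, nu / 2, nu * sigma0_sq / 2)
    }, numeric(1))
  }
  log(stats::integrate(f_s2, 0, Inf, rel.tol = 1e-8)$value)
}

# Exact posterior by dense enumeration: every configuration of every
# discrete node (filtered for consistency with the discrete evidence),
# continuous joint from the linear system via explicit matrix inversion,
# observed continuous values scored by the textbook MVN marginal density.
oracle_predict <- function(net, evidence, target) {
  nodes <- net$structure$nodes
  disc <- nodes[net$kinds[nodes] == "discrete"]
  cont <- nodes[net$kinds[nodes] == "continuous"]
  grid <- expand.grid(lapply(stats::setNames(disc, disc),
                             function(v) net$states[[v]]),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (v in intersect(names(evidence), disc))
    grid <- grid[grid[[v]] == evidence[[v]], , drop = FALSE]
  obs_cont <- intersect(names(evidence), cont)
  x_obs <- vapply(obs_cont, function(v) as.numeric(evidence[[v]]), numeric(1))

  weights <- stats::setNames(rep(0, length(net$states[[target]])),
                             net$states[[target]])
  for (g in seq_len(nrow(grid))) {
    assign <- as.list(grid[g, , drop = FALSE])
    w <- 1
    for (v in disc) {
      pc <- parent_configurations(net$structure, v, net)
      j <- 1L
      if (ncol(pc)) {
        hit <- rep(TRUE, nrow(pc))
        for (p in names(pc)) hit <- hit & pc[[p]] == assign[[p]]
        j <- which(hit)
      }
      k <- match(assign[[v]], net$states[[v]])
      w <- w * net$params[[v]]$cpt[j, k]
    }
    if (w > 0 && length(cont)) {
      nC <- length(cont)
      B <- matrix(0, nC, nC, dimnames = list(cont, cont))
      b0 <- stats::setNames(numeric(nC), cont)
      D <- matrix(0, nC, nC)
      for (i in seq_len(nC)) {
        v <- cont[[i]]
        pr <- net$params[[v]]
        pc <- parent_configurations(net$structure, v, net)
        j <- 1L
        if (ncol(pc)) {
          hit <- rep(TRUE, nrow(pc))
          for (p in names(pc)) hit <- hit & pc[[p]] == assign[[p]]
          j <- which(hit)
        }
        b0[i] <- pr$beta[j, 1L]
        if (length(pr$cont_parents))
          B[i, pr$cont_parents] <- pr$beta[j, -1L]
        D[i, i] <- pr$sigma2[j]
      }
      A <- solve(diag(nC) - B)
      mu <- as.numeric(A %*% b0)
      names(mu) <- cont
      Sigma <- A %*% D %*% t(A)
      dimnames(Sigma) <- list(cont, cont)
      if (length(obs_cont)) {
        S <- Sigma[obs_cont, obs_cont, drop = FALSE]
        d <- x_obs - mu[obs_cont]
        w <- w * (2 * pi)^(-length(obs_cont) / 2) * det(S)^(-1 / 2) *
          exp(-0.5 * as.numeric(t(d) %*% solve(S) %*% d))
      }
    }
    weights[[assign[[target]]]] <- weights[[assign[[target]]]] + w
  }
  weights / sum(weights)
}

# Mann-Whitney AUC by rank, used by the permutation reference.
rank_auc <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
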