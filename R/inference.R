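# Parameter learning for a fixed structure and exact posterior prediction of
# a discrete target. Prediction enumerates the configurations of the
# unobserved discrete variables and marginalizes unobserved continuous
# variables analytically (the joint over the continuous nodes is Gaussian
# once every discrete node is assigned), which is result-equivalent to
# junction-tree propagation in a conditional Gaussian network.

#' Fit network parameters by Bayesian posterior means
#'
#' Discrete nodes receive posterior-mean CPTs
#' `(N_ijk + a/(r q)) / (N_ij + a/q)`; continuous nodes receive, per
#' discrete-parent configuration, the posterior-mean regression coefficients
#' and the posterior-mean residual variance of the conjugate normal-inverse-
#' gamma model (`b_n / (a_n - 1)` when the posterior shape exceeds one,
#' `b_n / a_n` otherwise). Parent configurations with no observed rows fall
#' back to the prior: uniform CPT rows, zero coefficients, variance
#' `sigma0_sq`.
#'
#' @param structure a `cgbn_dag`, a legal conditional Gaussian skeleton over
#'   the dataset columns.
#' @param data a `mixed_data` object.
#' @param prior a `prior_hyper`.
#' @return An object of class `cgbn`: structure, per-node parameter tables,
#'   variable typing, phenotype name and the prior used.
#' @examples
#' md <- mixed_data(data.frame(p = c("a", "a", "b"), x = c(1, 2, 0)), "p")
#' net <- fit_parameters(dag(c("p", "x"), cbind("p", "x")), md)
#' net$params$x$beta0
#' @export
fit_parameters <- function(structure, data, prior = prior_hyper()) {
  if (!setequal(structure$nodes, var_names(data)))
    stop("structure nodes must match dataset columns")
  viol <- validate_cg_constraints(structure, data)
  if (length(viol)) stop("illegal CG structure: ", paste(viol, collapse = ", "))
  if (!is_acyclic(structure)) stop("structure is cyclic")

  params <- list()
  for (v in structure$nodes) {
    q <- n_configs(structure, v, data)
    j <- config_index_of(structure, v, data)
    if (is_discrete(data, v)) {
      st <- data$states[[v]]
      r <- length(st)
      k <- match(data$df[[v]], st)
      n_ijk <- matrix(tabulate((j - 1L) * r + k, nbins = q * r),
                      nrow = q, byrow = TRUE, dimnames = list(NULL, st))
      a_jk <- prior$alpha / (q * r)
      a_j <- prior$alpha / q
      cpt <- (n_ijk + a_jk) / (rowSums(n_ijk) + a_j)
      params[[v]] <- list(kind = "discrete", cpt = cpt)
    } else {
      cp <- continuous_parents(structure, v, data)
      p <- 1L + length(cp)
      y <- data$df[[v]]
      X <- cbind(1, as.matrix(data$df[cp]))
      beta <- matrix(0, nrow = q, ncol = p,
                     dimnames = list(NULL, c("(intercept)", cp)))
      sigma2 <- rep(prior$sigma0_sq, q)
      a0 <- prior$nu / 2
      b0 <- prior$nu * prior$sigma0_sq / 2
      for (jj in seq_len(q)) {
        rows <- which(j == jj)
        nj <- length(rows)
        if (nj == 0L) next
        Xj <- X[rows, , drop = FALSE]
        yj <- y[rows]
        lambda_n <- diag(prior$nu, p) + crossprod(Xj)
        ch <- chol(lambda_n)
        beta_n <- backsolve(ch, forwardsolve(t(ch), crossprod(Xj, yj)))
        a_n <- a0 + nj / 2
        b_n <- b0 + 0.5 * (sum(yj^2) - sum((ch %*% beta_n)^2))
        beta[jj, ] <- beta_n
        sigma2[jj] <- if (a_n > 1) b_n / (a_n - 1) else b_n / a_n
      }
      params[[v]] <- list(kind = "continuous", cont_parents = cp,
                          beta = beta, sigma2 = sigma2)
    }
  }
  structure(list(structure = structure, params = params, kinds = data$kinds,
                 states = data$states, phenotype = data$phenotype,
                 prior = prior),
            class = "cgbn")
}

#' @export
print.cgbn <- function(x, ...) {
  cat("Conditional Gaussian Bayesian network: ",
      length(x$structure$nodes), " nodes, ",
      n_edges(x$structure), " edges; phenotype '", x$phenotype, "'\n",
      sep = "")
  invisible(x)
}

# Per-row log density of one node's value given its parents' values,
# vectorized over the rows of `data` (all family members must be columns).
row_family_loglik <- function(net, data, node) {
  st <- net$structure
  j <- config_index_of(st, node, list(kinds = net$kinds, states = net$states,
                                      df = data$df), NULL)
  # config_index_of expects a mixed_data-shaped list; reuse data columns
  pr <- net$params[[node]]
  if (pr$kind == "discrete") {
    k <- match(data$df[[node]], net$states[[node]])
    if (anyNA(k)) stop("value of '", node, "' outside declared states")
    log(pr$cpt[cbind(j, k)])
  } else {
    mu <- pr$beta[j, 1L]
    for (i in seq_along(pr$cont_parents))
      mu <- mu + pr$beta[j, 1L + i] * data$df[[pr$cont_parents[i]]]
    stats::dnorm(data$df[[node]], mean = mu, sd = sqrt(pr$sigma2[j]), log = TRUE)
  }
}

#' Joint log density of a full assignment
#'
#' Factorized log density: the sum over discrete nodes of their log CPT
#' entries plus the sum over continuous nodes of conditional Gaussian log
#' densities. Every node must be assigned.
#'
#' @param net a fitted `cgbn`.
#' @param assignment named list (or one-row data frame) giving a value for
#'   every node: state labels for discrete nodes, reals for continuous nodes.
#' @return Scalar log density.
#' @export
joint_log_density <- function(net, assignment) {
  assignment <- as.list(assignment)
  miss <- setdiff(net$structure$nodes, names(assignment))
  if (length(miss)) stop("assignment missing node '", miss[1], "'")
  df <- as.data.frame(assignment[net$structure$nodes],
                      stringsAsFactors = FALSE, optional = TRUE)
  names(df) <- net$structure$nodes
  fake <- list(df = df, kinds = net$kinds, states = net$states)
  sum(vapply(net$structure$nodes,
             function(v) row_family_loglik(net, fake, v), numeric(1)))
}

# Mean vector and covariance matrix of the continuous nodes given a full
# discrete assignment, by topological recursion over the linear Gaussian
# system. Returns list(mean, cov, nodes).
continuous_joint_given_discrete <- function(net, disc_assign) {
  topo <- topo_order(net$structure)
  cont <- topo[net$kinds[topo] == "continuous"]
  m <- stats::setNames(numeric(length(cont)), cont)
  S <- matrix(0, length(cont), length(cont), dimnames = list(cont, cont))
  for (i in seq_along(cont)) {
    v <- cont[[i]]
    pr <- net$params[[v]]
    j <- config_index_of(net$structure, v,
                         list(kinds = net$kinds, states = net$states),
                         disc_assign)
    cp <- pr$cont_parents
    b0 <- pr$beta[j, 1L]
    if (length(cp)) {
      b <- pr$beta[j, -1L]
      m[i] <- b0 + sum(b * m[cp])
      prev <- cont[seq_len(i - 1L)]
      cross <- as.numeric(b %*% S[cp, prev, drop = FALSE])
      S[i, seq_len(i - 1L)] <- cross
      S[seq_len(i - 1L), i] <- cross
      S[i, i] <- pr$sigma2[j] + as.numeric(b %*% S[cp, cp, drop = FALSE] %*% b)
    } else {
      m[i] <- b0
      S[i, i] <- pr$sigma2[j]
    }
  }
  list(mean = m, cov = S, nodes = cont)
}

# log N(x | mu, Sigma) via Cholesky.
dmvnorm_log <- function(x, mu, Sigma) {
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), x - mu)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z * z)
}

#' Exact posterior over a discrete target given partial evidence
#'
#' Enumerates all configurations of the unobserved discrete variables
#' (including the target); for each configuration the unobserved continuous
#' variables are marginalized analytically and the observed continuous values
#' contribute their joint Gaussian density. The result equals Cowell-style
#' conditional Gaussian propagation; a guard refuses problems with more than
#' 2^20 discrete configurations.
#'
#' @param net a fitted `cgbn`.
#' @param evidence named list of observed values (state labels / reals); must
#'   not contain the target.
#' @param target discrete node to predict.
#' @return Named numeric vector of posterior probabilities over the target's
#'   states (sums to one).
#' @examples
#' md <- mixed_data(data.frame(p = c("a", "b"), x = c(-1, 1)), "p")
#' net <- fit_parameters(dag(c("p", "x"), cbind("p", "x")), md)
#' predict_posterior(net, list(x = 0.5), "p")
#' @export
predict_posterior <- function(net, evidence, target) {
  check_node(net$structure, target)
  if (net$kinds[[target]] != "discrete") stop("target must be discrete")
  evidence <- as.list(evidence)
  if (target %in% names(evidence)) stop("target must not appear in evidence")
  unknown <- setdiff(names(evidence), net$structure$nodes)
  if (length(unknown)) stop("evidence for unknown node '", unknown[1], "'")

  disc <- net$structure$nodes[net$kinds[net$structure$nodes] == "discrete"]
  cont <- net$structure$nodes[net$kinds[net$structure$nodes] == "continuous"]
  for (v in intersect(names(evidence), disc))
    if (!evidence[[v]] %in% net$states[[v]])
      stop("evidence state for '", v, "' outside declared states")

  unobs_disc <- setdiff(disc, names(evidence))       # includes target
  sizes <- vapply(unobs_disc, function(v) length(net$states[[v]]), numeric(1))
  if (prod(sizes) > 2^20)
    stop("inference complexity guard: > 2^20 discrete configurations")

  obs_cont <- intersect(cont, names(evidence))
  x_obs <- vapply(obs_cont, function(v) as.numeric(evidence[[v]]), numeric(1))

  grid <- if (length(unobs_disc))
    expand.grid(lapply(stats::setNames(unobs_disc, unobs_disc),
                       function(v) net$states[[v]]),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  else as.data.frame(matrix(nrow = 1L, ncol = 0L))

  tstates <- net$states[[target]]
  acc <- stats::setNames(rep(-Inf, length(tstates)), tstates)
  fake_spec <- list(kinds = net$kinds, states = net$states)
  for (g in seq_len(nrow(grid))) {
    assign <- c(evidence, as.list(grid[g, , drop = FALSE]))
    lw <- 0
    for (v in disc) {
      pr <- net$params[[v]]
      j <- config_index_of(net$structure, v, fake_spec, assign)
      k <- match(assign[[v]], net$states[[v]])
      lw <- lw + log(pr$cpt[j, k])
      if (!is.finite(lw)) break
    }
    if (is.finite(lw) && length(obs_cont)) {
      cj <- continuous_joint_given_discrete(net, assign)
      lw <- lw + dmvnorm_log(x_obs, cj$mean[obs_cont],
                             cj$cov[obs_cont, obs_cont, drop = FALSE])
    }
    ts <- assign[[target]]
    acc[[ts]] <- logsumexp2(acc[[ts]], lw)
  }
  z <- logsumexp(acc)
  if (!is.finite(z))
    stop("degenerate evidence: zero likelihood under every target state")
  out <- exp(acc - z)
  out / sum(out)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
logsumexp2 <- function(a, b) logsumexp(c(a, b))

#' Predict the phenotype for every row of a dataset
#'
#' Uses each row (minus the target) as evidence restricted to the target's
#' Markov blanket; with the whole blanket observed the posterior factorizes
#' over the target's own family and its children's families, so no discrete
#' summation is needed and the computation is vectorized over rows. Values of
#' variables outside the blanket provably cannot alter the posterior.
#'
#' @param net a fitted `cgbn`.
#' @param data a `mixed_data` object whose columns cover the Markov blanket
#'   of `target`.
#' @param target discrete node to predict (default: the network phenotype).
#' @return An object of class `cgbn_prediction`: list with `posterior`
#'   (matrix rows x target states), `predicted` (argmax state per row) and
#'   `target`.
#' @export
predict_dataset <- function(net, data, target = net$phenotype) {
  check_node(net$structure, target)
  mb <- markov_blanket(net$structure, target)
  miss <- setdiff(mb, var_names(data))
  if (length(miss))
    stop("dataset is missing Markov-blanket column '", miss[1], "'")
  st <- net$states[[target]]
  fam <- c(target, children_of(net$structure, target))
  ll <- matrix(0, nrow = n_rows(data), ncol = length(st),
               dimnames = list(NULL, st))
  work <- data
  for (s in st) {
    work$df[[target]] <- rep(s, n_rows(data))
    tot <- 0
    for (v in fam)
      tot <- tot + row_family_loglik(net, work, v)
    ll[, s] <- tot
  }
  post <- exp(ll - apply(ll, 1L, logsumexp))
  post <- post / rowSums(post)
  structure(list(posterior = post,
                 predicted = st[max.col(post, ties.method = "first")],
                 target = target),
            class = "cgbn_prediction")
}

#' @export
print.cgbn_prediction <- function(x, ...) {
  cat("Predictions for '", x$target, "': ", nrow(x$posterior), " rows, ",
      ncol(x$posterior), " states\n", sep = "")
  invisible(x)
}

#' @describeIn predict_dataset S3 `predict` method; returns the posterior
#'   probability matrix (or, with `type = "state"`, the argmax states).
#' @param object a fitted `cgbn`.
#' @param newdata a `mixed_data` object.
#' @param type `"posterior"` (default) or `"state"`.
#' @param ... unused.
#' @export
predict.cgbn <- function(object, newdata, type = c("posterior", "state"), ...) {
  type <- match.arg(type)
  res <- predict_dataset(object, newdata)
  if (type == "posterior") res$posterior else res$predicted
}
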