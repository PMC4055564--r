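# Bayesian marginal-likelihood family scores. Discrete children use the
# Dirichlet-multinomial (BDeu) closed form; continuous children use the
# conjugate normal-inverse-gamma linear regression marginal, one regression
# per discrete-parent configuration. All scores are natural logs.

#' Prior hyperparameters for network scoring
#'
#' @param alpha BDeu equivalent sample size (> 0). The total prior
#'   pseudo-count, spread uniformly over the cells of each CPT.
#' @param nu Gaussian prior precision pseudo-count (> 0): coefficients get a
#'   zero-mean normal prior with precision `nu` (in units of the residual
#'   precision), and the residual variance an inverse-gamma
#'   (`nu/2`, `nu * sigma0_sq / 2`) prior.
#' @param sigma0_sq prior scale for the residual variance (> 0).
#' @param max_parents per-node parent limit used by the structure searches.
#' @return An object of class `prior_hyper`.
#' @examples
#' prior_hyper(alpha = 2, max_parents = 2)
#' @export
prior_hyper <- function(alpha = 1, nu = 1, sigma0_sq = 1, max_parents = 3) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.numeric(nu) || nu <= 0) stop("nu must be > 0")
  if (!is.numeric(sigma0_sq) || sigma0_sq <= 0) stop("sigma0_sq must be > 0")
  if (max_parents < 0) stop("max_parents must be >= 0")
  structure(list(alpha = alpha, nu = nu, sigma0_sq = sigma0_sq,
                 max_parents = as.integer(max_parents)),
            class = "prior_hyper")
}

#' @export
print.prior_hyper <- function(x, ...) {
  cat(sprintf("Prior: alpha=%g, nu=%g, sigma0_sq=%g, max_parents=%d\n",
              x$alpha, x$nu, x$sigma0_sq, x$max_parents))
  invisible(x)
}

#' BDeu family score of a discrete child
#'
#' Log marginal likelihood of the child column under a Dirichlet-multinomial
#' with symmetric hyperparameters `alpha/(r*q)` per CPT cell (`r` child
#' states, `q` parent configurations):
#' sum over configurations j of
#' `lgamma(a/q) - lgamma(a/q + N_ij) + sum_k [lgamma(a/(rq) + N_ijk) -
#' lgamma(a/(rq))]`. Configurations with no rows contribute zero (the
#' marginal likelihood of no data is one).
#'
#' @param data a `mixed_data` object.
#' @param child name of a discrete column.
#' @param parents character vector of discrete parent names (may be empty).
#' @param prior a `prior_hyper`.
#' @return Log marginal likelihood (scalar).
#' @export
bdeu_family_score <- function(data, child, parents = character(0), prior = prior_hyper()) {
  if (!is_discrete(data, child)) stop("BDeu child '", child, "' must be discrete")
  for (p in parents)
    if (!is_discrete(data, p)) stop("BDeu parent '", p, "' must be discrete")
  r <- length(data$states[[child]])
  parents <- sort(unique(as.character(parents)))
  q <- if (length(parents)) prod(vapply(parents, function(p)
    length(data$states[[p]]), integer(1))) else 1L

  # joint cell index (config j, child state k), counted in one pass
  j <- rep(1L, n_rows(data))
  for (p in parents)
    j <- (j - 1L) * length(data$states[[p]]) + match(data$df[[p]], data$states[[p]])
  k <- match(data$df[[child]], data$states[[child]])
  n_ijk <- matrix(tabulate((j - 1L) * r + k, nbins = q * r),
                  nrow = q, byrow = TRUE)
  n_ij <- rowSums(n_ijk)

  a_j <- prior$alpha / q
  a_jk <- prior$alpha / (q * r)
  sum(lgamma(a_j) - lgamma(a_j + n_ij)) +
    sum(lgamma(a_jk + n_ijk) - lgamma(a_jk))
}

# Normal-inverse-gamma marginal likelihood of y ~ X beta, sigma^2 with
# beta | sigma^2 ~ N(0, sigma^2/nu I), sigma^2 ~ IG(nu/2, nu*sigma0^2/2).
nig_log_marginal <- function(y, X, prior) {
  n <- length(y)
  if (n == 0L) return(0)
  p <- ncol(X)
  nu <- prior$nu
  a0 <- nu / 2
  b0 <- nu * prior$sigma0_sq / 2
  lambda_n <- diag(nu, p) + crossprod(X)
  ch <- chol(lambda_n)
  beta_n <- backsolve(ch, forwardsolve(t(ch), crossprod(X, y)))
  b_n <- b0 + 0.5 * (sum(y * y) - sum((ch %*% beta_n)^2))
  a_n <- a0 + n / 2
  -(n / 2) * log(2 * pi) + (p / 2) * log(nu) - sum(log(diag(ch))) +
    a0 * log(b0) - a_n * log(b_n) + lgamma(a_n) - lgamma(a0)
}

#' Conditional linear Gaussian family score of a continuous child
#'
#' For each configuration of the discrete parents, the child rows are scored
#' by the marginal likelihood of a Bayesian linear regression on an intercept
#' plus the continuous parents, under the conjugate normal-inverse-gamma
#' prior of [prior_hyper()]; the family score is the sum of the per-
#' configuration log marginals. Empty configurations contribute zero.
#'
#' @param data a `mixed_data` object.
#' @param child name of a continuous column.
#' @param cont_parents continuous parent names (may be empty).
#' @param disc_parents discrete parent names (may be empty).
#' @param prior a `prior_hyper`.
#' @return Log marginal likelihood (scalar).
#' @export
clg_family_score <- function(data, child, cont_parents = character(0),
                             disc_parents = character(0), prior = prior_hyper()) {
  if (is_discrete(data, child)) stop("CLG child '", child, "' must be continuous")
  cont_parents <- sort(unique(as.character(cont_parents)))
  disc_parents <- sort(unique(as.character(disc_parents)))
  for (p in disc_parents)
    if (!is_discrete(data, p)) stop("'", p, "' is not discrete")
  for (p in cont_parents)
    if (is_discrete(data, p)) stop("'", p, "' is not continuous")

  j <- rep(1L, n_rows(data))
  for (p in disc_parents)
    j <- (j - 1L) * length(data$states[[p]]) + match(data$df[[p]], data$states[[p]])
  y <- data$df[[child]]
  X <- cbind(1, as.matrix(data$df[cont_parents]))

  total <- 0
  for (jj in unique(j)) {
    rows <- which(j == jj)
    total <- total + nig_log_marginal(y[rows], X[rows, , drop = FALSE], prior)
  }
  total
}

# Dispatch on child kind; parents split by kind internally.
family_score <- function(data, child, parents, prior) {
  parents <- as.character(parents)
  if (is_discrete(data, child)) {
    bdeu_family_score(data, child, parents, prior)
  } else {
    disc <- parents[vapply(parents, function(p) is_discrete(data, p), logical(1))]
    clg_family_score(data, child, setdiff(parents, disc), disc, prior)
  }
}

# Memoized family score bound to one dataset + prior. `counter` counts
# fresh evaluations (cache misses), used to verify search complexity bounds.
make_scorer <- function(data, prior) {
  cache <- new.env(parent = emptyenv())
  misses <- 0L
  score <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    misses <<- misses + 1L
    val <- family_score(data, child, parents, prior)
    cache[[key]] <- val
    val
  }
  list(score = score, n_evals = function() misses)
}

#' Total network score
#'
#' Sum of family scores over all nodes (the marginal likelihood decomposes
#' over families). The structure must be a legal conditional Gaussian
#' skeleton over the dataset's variables.
#'
#' @param structure a `cgbn_dag` over the dataset's columns.
#' @param data a `mixed_data` object.
#' @param prior a `prior_hyper`.
#' @return Log marginal likelihood of the data given the structure.
#' @export
network_score <- function(structure, data, prior = prior_hyper()) {
  if (!setequal(structure$nodes, var_names(data)))
    stop("structure nodes must match dataset columns")
  viol <- validate_cg_constraints(structure, data)
  if (length(viol))
    stop("illegal CG structure: ", paste(viol, collapse = ", "))
  if (!is_acyclic(structure)) stop("structure is cyclic")
  sum(vapply(structure$nodes, function(v)
    family_score(data, v, structure$parents[[v]], prior), numeric(1)))
}

#' Bayes-factor screen of candidate predictors
#'
#' For each candidate variable the log Bayes factor of dependence on the
#' phenotype: family score with the phenotype as sole parent minus the
#' parentless family score. Intended as a univariate filter that prunes
#' thousands of variables down to a tractable set before network search.
#'
#' @param data a `mixed_data` object.
#' @param phenotype discrete phenotype name (defaults to the dataset's).
#' @param candidates candidate variable names (default: all non-phenotype
#'   columns).
#' @param log_bf_threshold keep candidates with log Bayes factor strictly
#'   above this value (default 0, i.e. evidence must favour dependence).
#' @param prior a `prior_hyper`.
#' @return Data frame with columns `variable` and `log_bf`, sorted by
#'   descending `log_bf` (ties broken by name), containing only candidates
#'   above the threshold.
#' @export
bayes_factor_filter <- function(data, phenotype = data$phenotype,
                                candidates = setdiff(var_names(data), phenotype),
                                log_bf_threshold = 0,
                                prior = prior_hyper()) {
  if (phenotype %in% candidates)
    stop("phenotype cannot be its own candidate")
  if (!length(candidates))
    return(data.frame(variable = character(0), log_bf = numeric(0)))
  lbf <- vapply(candidates, function(v)
    family_score(data, v, phenotype, prior) -
      family_score(data, v, character(0), prior), numeric(1))
  ord <- order(-lbf, candidates)
  out <- data.frame(variable = candidates[ord], log_bf = lbf[ord],
                    row.names = NULL)
  out[out$log_bf > log_bf_threshold, , drop = FALSE]
}
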