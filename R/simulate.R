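# Synthetic-data engine: random conditional Gaussian networks, forward
# sampling, and equal-width discretization. The generator's defaults emulate
# the case-control benchmarks used throughout the package's validation: a
# binary phenotype with a large Markov blanket of strongly informative
# continuous children, plus background discrete/continuous structure.

#' Configuration for the random network generator
#'
#' Defaults describe a 20-variable case-control domain: 5 discrete variables
#' (one of which is the binary phenotype) and 15 continuous ones, a parent
#' limit of 3, and a phenotype that parents most other nodes so that its
#' Markov blanket is large and prediction from the true network is close to
#' the ceiling even at small training sizes.
#'
#' @param n_discrete number of discrete variables, phenotype included.
#' @param n_continuous number of continuous variables.
#' @param n_states states per non-phenotype discrete node (phenotype is
#'   always binary `"ctrl"`/`"case"` with a uniform marginal).
#' @param max_parents per-node parent cap during generation.
#' @param edge_prob probability of keeping each legal candidate edge from a
#'   non-phenotype node.
#' @param pheno_edge_prob probability that the phenotype parents any given
#'   later node (kept higher than `edge_prob` to produce the large blanket).
#' @param effect_range magnitude range for conditional Gaussian coefficients
#'   and for the intercept separation between adjacent discrete-parent
#'   configurations (the class signal).
#' @param sigma2_range range of the conditional Gaussian residual variances.
#' @param seed generator seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_discrete = 5L, n_continuous = 15L,
                             n_states = 2L, max_parents = 3L,
                             edge_prob = 0.25, pheno_edge_prob = 0.7,
                             effect_range = c(0.8, 1.3),
                             sigma2_range = c(0.8, 1.2), seed = 1L) {
  stopifnot(n_discrete >= 1L, n_continuous >= 0L, n_states >= 2L,
            max_parents >= 0L, edge_prob >= 0, edge_prob <= 1,
            pheno_edge_prob >= 0, pheno_edge_prob <= 1,
            length(effect_range) == 2L, effect_range[1] <= effect_range[2],
            length(sigma2_range) == 2L, sigma2_range[1] > 0)
  structure(list(n_discrete = as.integer(n_discrete),
                 n_continuous = as.integer(n_continuous),
                 n_states = as.integer(n_states),
                 max_parents = as.integer(max_parents),
                 edge_prob = edge_prob, pheno_edge_prob = pheno_edge_prob,
                 effect_range = effect_range, sigma2_range = sigma2_range,
                 seed = as.integer(seed)),
            class = "generator_config")
}

runif_signed <- function(n, range) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, range[1], range[2])
}

#' Generate a random conditional Gaussian network
#'
#' Nodes are laid out along a random permutation with the phenotype first;
#' candidate edges run only from earlier to later nodes (acyclic by
#' construction) and never from a continuous into a discrete node. Each later
#' node takes the phenotype as a parent with `pheno_edge_prob` and other
#' earlier nodes with `edge_prob`, up to `max_parents`. Discrete CPT rows are
#' drawn from a symmetric Dirichlet(1) (the phenotype marginal is uniform);
#' conditional Gaussian coefficients are uniform in plus/minus
#' `effect_range`, intercepts are separated across discrete-parent
#' configurations by a per-node step drawn from `effect_range` (this creates
#' the class signal), and residual variances are uniform in `sigma2_range`.
#'
#' @param cfg a `generator_config`.
#' @return A `cgbn` with phenotype `"pheno"`.
#' @examples
#' net <- random_cgbn(generator_config(seed = 42))
#' is_acyclic(net$structure)
#' @export
random_cgbn <- function(cfg = generator_config()) {
  set.seed(cfg$seed)
  nd <- cfg$n_discrete; nc <- cfg$n_continuous
  disc_names <- c("pheno", if (nd > 1L) paste0("D", seq_len(nd - 1L)))
  cont_names <- if (nc > 0L) paste0("X", seq_len(nc)) else character(0)
  nodes <- c(disc_names, cont_names)
  kinds <- stats::setNames(c(rep("discrete", nd), rep("continuous", nc)), nodes)
  states <- stats::setNames(
    c(list(c("ctrl", "case")),
      rep(list(paste0("s", seq_len(cfg$n_states))), nd - 1L)),
    disc_names)

  perm <- c("pheno", sample(setdiff(nodes, "pheno")))
  g <- dag(nodes)
  for (i in seq_along(perm)[-1L]) {
    child <- perm[[i]]
    earlier <- perm[seq_len(i - 1L)]
    cand <- earlier[vapply(earlier, function(u)
      !(kinds[[child]] == "discrete" && kinds[[u]] == "continuous"),
      logical(1))]
    # phenotype considered first, at its own inclusion rate
    cand <- c(intersect(cand, "pheno"), setdiff(cand, "pheno"))
    for (u in cand) {
      if (length(g$parents[[child]]) >= cfg$max_parents) break
      # the phenotype preferentially drives the continuous (omics) layer;
      # discrete background nodes connect at the baseline rate
      p <- if (u == "pheno" && kinds[[child]] == "continuous")
        cfg$pheno_edge_prob else cfg$edge_prob
      if (stats::runif(1) < p) g <- add_edge(g, u, child)
    }
  }

  spec <- list(kinds = kinds, states = states)
  params <- list()
  for (v in nodes) {
    dp <- sort(g$parents[[v]][kinds[g$parents[[v]]] == "discrete"])
    q <- if (length(dp)) prod(vapply(dp, function(p) length(states[[p]]),
                                     integer(1))) else 1L
    if (kinds[[v]] == "discrete") {
      r <- length(states[[v]])
      if (v == "pheno") {
        cpt <- matrix(1 / r, nrow = q, ncol = r)
      } else {
        cpt <- matrix(stats::rgamma(q * r, shape = 1), nrow = q)
        cpt <- cpt / rowSums(cpt)
      }
      colnames(cpt) <- states[[v]]
      params[[v]] <- list(kind = "discrete", cpt = cpt)
    } else {
      cp <- sort(g$parents[[v]][kinds[g$parents[[v]]] == "continuous"])
      base <- stats::rnorm(1)
      step <- stats::runif(1, cfg$effect_range[1], cfg$effect_range[2])
      beta <- matrix(0, nrow = q, ncol = 1L + length(cp),
                     dimnames = list(NULL, c("(intercept)", cp)))
      beta[, 1L] <- base + step * (seq_len(q) - (q + 1) / 2)
      if (length(cp))
        for (jj in seq_len(q))
          beta[jj, -1L] <- runif_signed(length(cp), cfg$effect_range)
      params[[v]] <- list(kind = "continuous", cont_parents = cp, beta = beta,
                          sigma2 = stats::runif(q, cfg$sigma2_range[1],
                                                cfg$sigma2_range[2]))
    }
  }
  cgbn(g, params, kinds, states, phenotype = "pheno")
}

#' Forward-sample a dataset from a network
#'
#' Samples rows in topological order: discrete nodes from their CPT row for
#' the sampled parent configuration, continuous nodes from the conditional
#' linear Gaussian of their configuration.
#'
#' @param net a `cgbn`.
#' @param n number of rows.
#' @param seed sampling seed.
#' @return A `mixed_data` with the network's variables, state lists and
#'   phenotype.
#' @export
sample_dataset <- function(net, n, seed = 1L) {
  stopifnot(n >= 1L)
  set.seed(seed)
  topo <- topo_order(net$structure)
  df <- as.data.frame(matrix(nrow = n, ncol = 0L))
  spec <- list(kinds = net$kinds, states = net$states)
  for (v in topo) {
    spec$df <- df
    j <- config_index_of2(net$structure, v, spec, n)
    pr <- net$params[[v]]
    if (net$kinds[[v]] == "discrete") {
      st <- net$states[[v]]
      u <- stats::runif(n)
      cum <- t(apply(pr$cpt, 1L, cumsum))
      k <- pmin(rowSums(u > cum[j, , drop = FALSE]) + 1L, length(st))
      df[[v]] <- st[k]
    } else {
      mu <- pr$beta[j, 1L]
      for (i in seq_along(pr$cont_parents))
        mu <- mu + pr$beta[j, 1L + i] * df[[pr$cont_parents[i]]]
      df[[v]] <- stats::rnorm(n, mean = mu, sd = sqrt(pr$sigma2[j]))
    }
  }
  df <- df[, net$structure$nodes, drop = FALSE]
  mixed_data(df, phenotype = net$phenotype, kinds = net$kinds,
             states = net$states)
}

# config_index_of for an n-row partial frame during sampling
config_index_of2 <- function(structure, node, spec, n) {
  dp <- sort(structure$parents[[node]][
    spec$kinds[structure$parents[[node]]] == "discrete"])
  if (!length(dp)) return(rep(1L, n))
  idx <- rep(1L, n)
  for (p in dp) {
    st <- spec$states[[p]]
    idx <- (idx - 1L) * length(st) + match(spec$df[[p]], st)
  }
  idx
}

#' Equal-width discretization of the continuous columns
#'
#' Each continuous column is cut into `bins` equal-width intervals between
#' its minimum and maximum; values map to bin labels `"1"` to
#' `"<bins>"`, with the maximum assigned to the last bin. When `edges`
#' from a previous (training-set) call are supplied they are reused and
#' out-of-range values are clipped into the first/last bin, so test data are
#' binned on the training grid without leakage. Discretized columns declare
#' the full `1..bins` state list so that parameter tables learned on one
#' dataset apply to another binned on the same grid.
#'
#' @param data a `mixed_data` object.
#' @param bins number of bins (default 10).
#' @param edges optional named list of numeric break vectors (as stored in
#'   the `"bin_edges"` attribute of a previous result).
#' @return A `mixed_data` with every column discrete; attribute
#'   `"bin_edges"` holds the break vectors for reuse on test data.
#' @export
discretize_equal_width <- function(data, bins = 10L, edges = NULL) {
  stopifnot(bins >= 2L)
  df <- data$df
  kinds <- data$kinds
  states <- data$states
  out_edges <- list()
  for (v in var_names(data)[data$kinds == "continuous"]) {
    x <- df[[v]]
    br <- if (!is.null(edges) && !is.null(edges[[v]])) edges[[v]]
          else seq(min(x), max(x), length.out = bins + 1L)
    out_edges[[v]] <- br
    if (br[1L] == br[length(br)]) {
      warning("constant column '", v, "' collapses to a single bin")
      b <- rep(1L, length(x))
      states[[v]] <- "1"
    } else {
      w <- (br[length(br)] - br[1L]) / bins
      b <- pmin(pmax(floor((x - br[1L]) / w) + 1L, 1L), bins)
      states[[v]] <- as.character(seq_len(bins))
    }
    df[[v]] <- as.character(b)
    kinds[[v]] <- "discrete"
  }
  out <- structure(list(df = df, kinds = kinds, states = states,
                        phenotype = data$phenotype),
                   class = "mixed_data")
  attr(out, "bin_edges") <- out_edges
  out
}
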