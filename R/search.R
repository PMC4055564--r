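# Structure learning: K2 ordered search with stepwise parent replacement,
# greedy exhaustive hill-climbing, phenotype-centric Markov-blanket search,
# and simulated annealing. All moves respect acyclicity (DFS check), the
# conditional Gaussian restriction and the max-parents limit; scores are
# memoized per family so repeated candidate evaluations are free.

#' Configuration for a structure search
#'
#' @param algorithm one of `"k2"`, `"greedy"`, `"pheno_centric"`,
#'   `"annealing"`, or `"naive_bayes"` (the convenience topology with the
#'   phenotype as sole parent of every other variable).
#' @param prior a `prior_hyper` (carries the max-parents limit).
#' @param backtracking allow edge removals in the greedy search.
#' @param proposals proposal budget for simulated annealing (default: cube of
#'   the number of variables).
#' @param seed integer seed for the stochastic searches and for fold/bootstrap
#'   machinery built on top.
#' @param phenotype phenotype column name (default: taken from the dataset).
#' @return An object of class `search_config`.
#' @export
search_config <- function(algorithm = c("greedy", "k2", "pheno_centric",
                                        "annealing", "naive_bayes"),
                          prior = prior_hyper(), backtracking = FALSE,
                          proposals = NULL, seed = 1L, phenotype = NULL) {
  algorithm <- match.arg(algorithm)
  structure(list(algorithm = algorithm, prior = prior,
                 backtracking = isTRUE(backtracking),
                 proposals = proposals, seed = as.integer(seed),
                 phenotype = phenotype),
            class = "search_config")
}

legal_parent <- function(data, parent, child) {
  # continuous nodes may not parent discrete nodes
  !(is_discrete(data, child) && !is_discrete(data, parent))
}

#' K2 node ordering
#'
#' Orders the variables for the K2 search: the phenotype first (so it can
#' acquire many children and no parents — the topology that predicts best),
#' then the remaining variables by ascending log Bayes factor of dependence
#' on the phenotype, most-independent earliest, ties broken by name. Nodes
#' may only take parents that precede them in this order.
#'
#' @param data a `mixed_data` object.
#' @param phenotype discrete phenotype name.
#' @param prior a `prior_hyper`.
#' @return Character vector: a permutation of all variable names with the
#'   phenotype in position one.
#' @export
k2_order <- function(data, phenotype = data$phenotype, prior = prior_hyper()) {
  others <- setdiff(var_names(data), phenotype)
  if (!length(others)) return(phenotype)
  lbf <- vapply(others, function(v)
    family_score(data, v, phenotype, prior) -
      family_score(data, v, character(0), prior), numeric(1))
  c(phenotype, others[order(lbf, others)])
}

#' K2 ordered structure search
#'
#' For each child (continuous children first, then discrete, each in order)
#' the best preceding-node parent is added greedily while the family score
#' improves; once the parent limit binds, a stepwise swap (add one candidate,
#' drop one existing parent) is considered if it strictly improves the score.
#' The ordering constraint makes cycles impossible by construction.
#'
#' @param data a `mixed_data` object.
#' @param order a permutation of the variable names (see [k2_order()]).
#' @param config a `search_config`.
#' @return A `cgbn_dag` with attributes `n_evals` (family-score evaluations)
#'   and `score` (total network score).
#' @export
learn_k2 <- function(data, order = k2_order(data, prior = config$prior),
                     config = search_config("k2")) {
  nodes <- var_names(data)
  if (!setequal(order, nodes) || length(order) != length(nodes))
    stop("order must be a permutation of the variable names")
  sc <- make_scorer(data, config$prior)
  kmax <- config$prior$max_parents
  g <- dag(nodes)

  learn_child <- function(g, child) {
    pos <- match(child, order)
    cand_all <- order[seq_len(pos - 1L)]
    cand_all <- cand_all[vapply(cand_all, legal_parent, logical(1),
                                data = data, child = child)]
    parents <- character(0)
    best <- sc$score(child, parents)
    repeat {
      moved <- FALSE
      avail <- setdiff(cand_all, parents)
      if (length(parents) < kmax && length(avail)) {
        vals <- vapply(avail, function(c) sc$score(child, c(parents, c)),
                       numeric(1))
        i <- order(-vals, avail)[1L]
        if (vals[[i]] > best) {
          parents <- sort(c(parents, avail[[i]]))
          best <- vals[[i]]
          moved <- TRUE
        }
      }
      if (!moved && length(parents) == kmax && kmax > 0L && length(avail)) {
        # stepwise replacement, only when the limit binds
        sw_best <- best; sw_add <- NA_character_; sw_drop <- NA_character_
        for (c in avail) for (p in parents) {
          v <- sc$score(child, c(setdiff(parents, p), c))
          if (v > sw_best) { sw_best <- v; sw_add <- c; sw_drop <- p }
        }
        if (!is.na(sw_add)) {
          parents <- sort(c(setdiff(parents, sw_drop), sw_add))
          best <- sw_best
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    g$parents[[child]] <- parents
    g
  }

  for (child in order[vapply(order, function(v) !is_discrete(data, v), logical(1))])
    g <- learn_child(g, child)
  for (child in order[vapply(order, function(v) is_discrete(data, v), logical(1))])
    g <- learn_child(g, child)

  stopifnot(is_acyclic(g))
  attr(g, "n_evals") <- sc$n_evals()
  attr(g, "score") <- sum(vapply(nodes, function(v)
    sc$score(v, g$parents[[v]]), numeric(1)))
  g
}

#' Greedy exhaustive hill-climbing search
#'
#' Starts from the empty network and repeatedly applies the single legal edge
#' addition (or, with backtracking, removal) with the largest strictly
#' positive score gain, until no move improves. Legality = acyclicity
#' (depth-first search), the conditional Gaussian restriction and the parent
#' limit. Ties are broken by lexicographic (parent, child) order, additions
#' before removals.
#'
#' @param data a `mixed_data` object.
#' @param config a `search_config`.
#' @return A `cgbn_dag` with attributes `n_evals`, `score`,
#'   `score_trajectory` (network score after each accepted move) and
#'   `max_sweep_evals` (most candidate moves examined in one sweep).
#' @export
learn_greedy_exhaustive <- function(data, config = search_config("greedy")) {
  nodes <- sort(var_names(data))
  sc <- make_scorer(data, config$prior)
  kmax <- config$prior$max_parents
  g <- dag(var_names(data))
  fam <- vapply(stats::setNames(nodes, nodes),
                function(v) sc$score(v, character(0)), numeric(1))
  total <- sum(fam)
  trajectory <- total
  max_sweep <- 0L

  repeat {
    best_delta <- 0; best_move <- NULL; sweep <- 0L
    for (u in nodes) for (v in nodes) {
      if (u == v) next
      if (has_edge(g, u, v)) {
        if (!config$backtracking) next
        sweep <- sweep + 1L
        d <- sc$score(v, setdiff(g$parents[[v]], u)) - fam[[v]]
        if (d > best_delta) { best_delta <- d; best_move <- c("drop", u, v) }
      } else {
        if (!legal_parent(data, u, v)) next
        if (length(g$parents[[v]]) >= kmax) next
        if (creates_cycle(g, u, v)) next
        sweep <- sweep + 1L
        d <- sc$score(v, c(g$parents[[v]], u)) - fam[[v]]
        if (d > best_delta) { best_delta <- d; best_move <- c("add", u, v) }
      }
    }
    max_sweep <- max(max_sweep, sweep)
    if (is.null(best_move)) break
    u <- best_move[2L]; v <- best_move[3L]
    g <- if (best_move[1L] == "add") add_edge(g, u, v) else remove_edge(g, u, v)
    fam[[v]] <- sc$score(v, g$parents[[v]])
    total <- total + best_delta
    trajectory <- c(trajectory, total)
  }
  stopifnot(is_acyclic(g))
  attr(g, "n_evals") <- sc$n_evals()
  attr(g, "score") <- total
  attr(g, "score_trajectory") <- trajectory
  attr(g, "max_sweep_evals") <- max_sweep
  g
}

#' Phenotype-centric Markov-blanket search
#'
#' Builds only the part of the network needed to predict the phenotype:
#' first phenotype-to-variable edges are added greedily by score gain, then
#' for each accepted child the co-parent edges (other variables into that
#' child) are added greedily under the same legality rules. The phenotype
#' never receives parents and every edge in the result touches its Markov
#' blanket.
#'
#' @param data a `mixed_data` object.
#' @param phenotype discrete phenotype name.
#' @param config a `search_config`.
#' @return A `cgbn_dag` with attributes `n_evals` and `score`.
#' @export
learn_pheno_centric <- function(data, phenotype = data$phenotype,
                                config = search_config("pheno_centric")) {
  nodes <- sort(var_names(data))
  sc <- make_scorer(data, config$prior)
  kmax <- config$prior$max_parents
  g <- dag(var_names(data))
  fam <- vapply(stats::setNames(nodes, nodes),
                function(v) sc$score(v, character(0)), numeric(1))
  children <- character(0)

  # stage 1: phenotype -> v edges, best-first while improving
  if (kmax > 0L) repeat {
    avail <- setdiff(nodes, c(phenotype, children))
    if (!length(avail)) break
    d <- vapply(avail, function(v) sc$score(v, phenotype) - fam[[v]], numeric(1))
    i <- order(-d, avail)[1L]
    if (d[[i]] <= 0) break
    v <- avail[[i]]
    g <- add_edge(g, phenotype, v)
    fam[[v]] <- fam[[v]] + d[[i]]
    children <- c(children, v)
  }

  # stage 2: co-parents of each accepted child
  for (v in children) {
    repeat {
      avail <- setdiff(nodes, c(v, g$parents[[v]]))
      avail <- avail[vapply(avail, legal_parent, logical(1),
                            data = data, child = v)]
      avail <- avail[!vapply(avail, creates_cycle, logical(1),
                             structure = g, child = v)]
      if (length(g$parents[[v]]) >= kmax || !length(avail)) break
      d <- vapply(avail, function(u)
        sc$score(v, c(g$parents[[v]], u)) - fam[[v]], numeric(1))
      i <- order(-d, avail)[1L]
      if (d[[i]] <= 0) break
      g <- add_edge(g, avail[[i]], v)
      fam[[v]] <- fam[[v]] + d[[i]]
    }
  }
  stopifnot(is_acyclic(g), !length(g$parents[[phenotype]]))
  attr(g, "n_evals") <- sc$n_evals()
  attr(g, "score") <- sum(vapply(nodes, function(v)
    sc$score(v, g$parents[[v]]), numeric(1)))
  g
}

#' Simulated annealing structure search
#'
#' Random-restart-free annealing over single-edge moves: at each step a legal
#' edge addition or removal is proposed uniformly; improving moves are always
#' accepted and worsening moves with probability `exp(delta / T)`, where the
#' temperature follows a geometric schedule from an initial value calibrated
#' as the median absolute score change of 100 random probe proposals down to
#' a floor near zero. The best-scoring structure visited is returned, not the
#' final one.
#'
#' @param data a `mixed_data` object.
#' @param config a `search_config`; `config$proposals` caps the number of
#'   proposals (default: number of variables cubed) and `config$seed` makes
#'   the run reproducible.
#' @param t0,cooling,t_floor annealing schedule: initial temperature
#'   (default: probe-calibrated), geometric cooling factor per proposal
#'   (default: chosen so the temperature reaches the floor exactly at the end
#'   of the budget, keeping the schedule meaningful for any budget), and
#'   temperature floor.
#' @return A `cgbn_dag` with attributes `n_evals` and `score`.
#' @export
learn_simulated_annealing <- function(data, config = search_config("annealing"),
                                      t0 = NULL, cooling = NULL,
                                      t_floor = 1e-8) {
  nodes <- sort(var_names(data))
  n <- length(nodes)
  budget <- if (is.null(config$proposals)) n^3 else config$proposals
  stopifnot(budget > 0)
  set.seed(config$seed)
  sc <- make_scorer(data, config$prior)
  kmax <- config$prior$max_parents
  g <- dag(var_names(data))
  fam <- vapply(stats::setNames(nodes, nodes),
                function(v) sc$score(v, character(0)), numeric(1))
  total <- sum(fam)
  best_g <- g; best_total <- total

  propose <- function(g) {
    u <- sample(nodes, 1L); v <- sample(setdiff(nodes, u), 1L)
    if (has_edge(g, u, v)) return(list(type = "drop", u = u, v = v))
    if (!legal_parent(data, u, v) || length(g$parents[[v]]) >= kmax ||
        creates_cycle(g, u, v)) return(NULL)
    list(type = "add", u = u, v = v)
  }

  if (is.null(t0)) {
    # probe the move landscape from the start state
    deltas <- numeric(0)
    for (i in seq_len(100L)) {
      mv <- propose(g)
      if (is.null(mv)) next
      p2 <- if (mv$type == "add") c(g$parents[[mv$v]], mv$u)
            else setdiff(g$parents[[mv$v]], mv$u)
      deltas <- c(deltas, abs(sc$score(mv$v, p2) - fam[[mv$v]]))
    }
    t0 <- if (length(deltas)) max(stats::median(deltas), t_floor) else 1
  }

  if (is.null(cooling)) cooling <- (t_floor / t0)^(1 / budget)
  temp <- t0
  for (i in seq_len(budget)) {
    temp <- max(temp * cooling, t_floor)
    mv <- propose(g)
    if (is.null(mv)) next
    p2 <- if (mv$type == "add") c(g$parents[[mv$v]], mv$u)
          else setdiff(g$parents[[mv$v]], mv$u)
    delta <- sc$score(mv$v, p2) - fam[[mv$v]]
    if (delta > 0 || stats::runif(1) < exp(delta / temp)) {
      g <- if (mv$type == "add") add_edge(g, mv$u, mv$v)
           else remove_edge(g, mv$u, mv$v)
      fam[[mv$v]] <- fam[[mv$v]] + delta
      total <- total + delta
      if (total > best_total) { best_total <- total; best_g <- g }
    }
  }
  stopifnot(is_acyclic(best_g))
  attr(best_g, "n_evals") <- sc$n_evals()
  attr(best_g, "score") <- best_total
  best_g
}

#' Naive Bayes topology
#'
#' The phenotype as sole parent of every listed predictor: predictors are
#' conditionally independent given the phenotype. Simple, immune to data
#' fragmentation, and in practice often an excellent predictor.
#'
#' @param data a `mixed_data` object.
#' @param phenotype discrete phenotype name.
#' @param predictors variables to attach (default: all others).
#' @return A `cgbn_dag`.
#' @export
naive_bayes_structure <- function(data, phenotype = data$phenotype,
                                  predictors = setdiff(var_names(data), phenotype)) {
  g <- dag(var_names(data))
  for (v in predictors) g <- add_edge(g, phenotype, v)
  g
}

#' Learn a network structure with any of the search algorithms
#'
#' Dispatcher over [learn_k2()], [learn_greedy_exhaustive()],
#' [learn_pheno_centric()], [learn_simulated_annealing()] and
#' [naive_bayes_structure()].
#'
#' @param data a `mixed_data` object.
#' @param config a `search_config`.
#' @return A `cgbn_dag` (with the search's instrumentation attributes).
#' @export
learn_network <- function(data, config = search_config()) {
  phenotype <- if (is.null(config$phenotype)) data$phenotype else config$phenotype
  switch(config$algorithm,
    k2 = learn_k2(data, k2_order(data, phenotype, config$prior), config),
    greedy = learn_greedy_exhaustive(data, config),
    pheno_centric = learn_pheno_centric(data, phenotype, config),
    annealing = learn_simulated_annealing(data, config),
    naive_bayes = naive_bayes_structure(data, phenotype),
    stop("unknown algorithm '", config$algorithm, "'"))
}
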