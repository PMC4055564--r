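# Bootstrap edge-frequency estimation and consensus-network construction:
# learn one network per bootstrap resample, count how often each directed
# edge appears, then rebuild a single network by adding edges in descending
# frequency and tracking cross-validated AUC after each addition.

#' Bootstrap edge frequencies
#'
#' Draws `B` bootstrap resamples of the rows (with replacement), learns one
#' structure per resample with the configured algorithm, and reports the
#' fraction of resamples in which each directed edge appears. A resample that
#' loses a phenotype class entirely is redrawn (and the redraw logged), since
#' no case-control structure can be learned from it.
#'
#' @param data a `mixed_data` object.
#' @param config a `search_config`.
#' @param B number of bootstrap realizations (default 25; large studies use
#'   a few thousand).
#' @param seed resampling seed.
#' @return An object of class `edge_freq`: data frame `edges` with columns
#'   `parent`, `child`, `count`, `freq` (sorted by descending frequency,
#'   ties by parent then child name), plus `B`.
#' @export
bootstrap_networks <- function(data, config = search_config(), B = 25L,
                               seed = config$seed) {
  stopifnot(B >= 1L)
  set.seed(seed)
  n <- n_rows(data)
  pheno <- data$df[[data$phenotype]]
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(pheno[idx])) == length(unique(pheno))) break
      message("bootstrap_networks: resample ", b,
              " lost a phenotype class; redrawn")
    }
    draws[[b]] <- idx
  }
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    cfg <- config
    cfg$seed <- config$seed + b
    g <- learn_network(subset_rows(data, draws[[b]]), cfg)
    em <- edge_matrix(g)
    for (r in seq_len(nrow(em))) {
      key <- paste(em[r, 1L], em[r, 2L], sep = "\r")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  if (length(keys)) {
    pc <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    cnt <- vapply(keys, function(k) counts[[k]], integer(1))
    edges <- data.frame(parent = pc[, 1L], child = pc[, 2L], count = cnt,
                        freq = cnt / B, row.names = NULL)
    edges <- edges[order(-edges$freq, edges$parent, edges$child), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(parent = character(0), child = character(0),
                        count = integer(0), freq = numeric(0))
  }
  structure(list(edges = edges, B = B), class = "edge_freq")
}

#' @export
print.edge_freq <- function(x, ...) {
  cat("Bootstrap edge frequencies over B = ", x$B, " realizations (",
      nrow(x$edges), " distinct edges)\n", sep = "")
  print(utils::head(x$edges, 10L))
  invisible(x)
}

#' Consensus network by descending bootstrap edge frequency
#'
#' Starting from the empty structure, edges are added in descending bootstrap
#' frequency (ties by parent, then child name); edges that would create a
#' cycle or violate the conditional Gaussian restriction are passed over and
#' the procedure continues down the list. After each accepted edge the
#' network parameters are refit and the cross-validated AUC of the (fixed)
#' structure is recorded, yielding a nested sequence of networks from which
#' the point of diminishing returns can be read off.
#'
#' @param freqs an `edge_freq` table.
#' @param data the `mixed_data` to evaluate on.
#' @param phenotype discrete phenotype (default: dataset's).
#' @param max_edges cap on the number of accepted edges.
#' @param config a `search_config` (prior for parameter fitting, seed for CV
#'   folds).
#' @param folds CV folds used at each step.
#' @return An object of class `consensus_path`: list with `steps`, a data
#'   frame (`parent`, `child`, `freq`, `n_edges`, `cv_auc`), and
#'   `structures`, the nested list of `cgbn_dag`s after each addition.
#' @export
consensus_network <- function(freqs, data, phenotype = data$phenotype,
                              max_edges = Inf, config = search_config(),
                              folds = 5L) {
  stopifnot(inherits(freqs, "edge_freq"))
  if (!nrow(freqs$edges)) stop("empty edge-frequency table")
  g <- dag(var_names(data))
  steps <- list()
  structures <- list()
  for (r in seq_len(nrow(freqs$edges))) {
    if (length(structures) >= max_edges) break
    u <- freqs$edges$parent[r]; v <- freqs$edges$child[r]
    if (!legal_parent(data, u, v) || creates_cycle(g, u, v)) next
    g <- add_edge(g, u, v)
    cv <- cross_validate(data, config, folds = folds, seed = config$seed,
                         structure = g)
    structures[[length(structures) + 1L]] <- g
    steps[[length(steps) + 1L]] <- data.frame(
      parent = u, child = v, freq = freqs$edges$freq[r],
      n_edges = n_edges(g), cv_auc = cv$pooled_auc)
  }
  structure(list(steps = do.call(rbind, steps), structures = structures),
            class = "consensus_path")
}

#' @export
print.consensus_path <- function(x, ...) {
  cat("Consensus-network path (", nrow(x$steps), " edges)\n", sep = "")
  print(x$steps)
  invisible(x)
}
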