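# Model validation: ROC/AUC with convex hull and DeLong 95% CI, the DeLong
# paired test for two AUCs on the same rows, and stratified k-fold
# cross-validation (performance estimation and prior-hyperparameter tuning).

coerce_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) != 2L)
    stop("labels must contain exactly two classes (got ", length(u), ")")
  # second value in sort order is the positive class (e.g. 0/1, "case" after
  # "abc..." only by accident -- callers in this package pass 0/1)
  as.integer(labels == u[[2L]])
}

# DeLong structural components: V10 per positive, V01 per negative.
delong_components <- function(scores, y) {
  pos <- scores[y == 1L]
  neg <- scores[y == 0L]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve, AUC, convex hull and 95% confidence interval
#'
#' AUC is the Mann-Whitney statistic (ties counted one half); the convex-hull
#' AUC is the area under the upper convex envelope of the ROC points (the
#' performance achievable by randomizing between thresholds); the confidence
#' interval is the DeLong asymptotic normal interval, clipped to \[0, 1\].
#'
#' @param scores numeric prediction scores, higher = more positive.
#' @param labels binary labels (0/1, logical, or two distinct values; the
#'   larger/later value is the positive class).
#' @return An object of class `roc_analysis`: `points` (data frame of FPR,
#'   TPR from (0,0) to (1,1)), `auc`, `convex_hull_auc`, `se`, `ci95`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc
#' @export
roc_auc <- function(scores, labels) {
  y <- coerce_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y); n0 <- sum(1L - y)

  comp <- delong_components(scores, y)
  auc <- comp$auc
  s10 <- if (n1 > 1L) stats::var(comp$v10) else 0
  s01 <- if (n0 > 1L) stats::var(comp$v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  ci <- pmin(pmax(auc + c(-1, 1) * 1.96 * se, 0), 1)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(y == 1L & scores >= t) / n1, numeric(1)))
  fpr <- c(0, vapply(thr, function(t) sum(y == 0L & scores >= t) / n0, numeric(1)))
  pts <- data.frame(fpr = fpr, tpr = tpr)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  rownames(pts) <- NULL

  hull <- upper_hull(pts$fpr, pts$tpr)
  structure(list(points = pts, auc = auc,
                 convex_hull_auc = trapezoid_area(hull$x, hull$y),
                 se = se, ci95 = c(lower = ci[1L], upper = ci[2L])),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("AUC %.4f (95%% CI %.4f-%.4f), convex hull %.4f\n",
              x$auc, x$ci95[["lower"]], x$ci95[["upper"]], x$convex_hull_auc))
  invisible(x)
}

# Upper convex envelope from (0,0) to (1,1) (Andrew's monotone chain).
upper_hull <- function(x, y) {
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_along(x)) {
    while (length(hx) >= 2L) {
      m <- length(hx)
      cross <- (hx[m] - hx[m - 1L]) * (y[i] - hy[m - 1L]) -
               (hy[m] - hy[m - 1L]) * (x[i] - hx[m - 1L])
      if (cross >= 0) { hx <- hx[-m]; hy <- hy[-m] } else break
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  list(x = hx, y = hy)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided test of equality of the AUCs of two score vectors computed on
#' the same rows, using the asymptotic normal statistic built from the
#' DeLong structural components (which account for the correlation induced by
#' sharing the data). Identical score vectors return p = 1 by convention; a
#' degenerate zero-variance difference with unequal AUCs returns the limiting
#' p = 0.
#'
#' @param scores_a,scores_b paired prediction scores on identical rows.
#' @param labels binary labels.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- coerce_binary_labels(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("scores and labels differ in length")
  ca <- delong_components(scores_a, y)
  cb <- delong_components(scores_b, y)
  if (isTRUE(all.equal(scores_a, scores_b)))
    return(list(auc_a = ca$auc, auc_b = cb$auc, z = 0, p_value = 1))
  n1 <- sum(y); n0 <- sum(1L - y)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  s <- s10 / n1 + s01 / n0
  v <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- ca$auc - cb$auc
  if (v <= 0) {
    p <- if (abs(d) < .Machine$double.eps^0.5) 1 else 0
    return(list(auc_a = ca$auc, auc_b = cb$auc, z = if (p == 1) 0 else Inf * sign(d),
                p_value = p))
  }
  z <- d / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

# Seeded stratified fold assignment: within each class, shuffled rows are
# dealt round-robin over folds. Returns integer vector of fold ids.
stratified_folds <- function(labels, folds, seed) {
  y <- as.character(labels)
  if (any(table(y) < folds))
    stop("stratification infeasible: a class has fewer rows than folds")
  set.seed(seed)
  assign <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    rows <- rows[sample.int(length(rows))]
    assign[rows] <- rep_len(seq_len(folds), length(rows))
  }
  assign
}

positive_state <- function(data) {
  st <- data$states[[data$phenotype]]
  if (length(st) != 2L)
    stop("AUC-based validation requires a binary phenotype")
  st[[2L]]
}

# Learn + fit on training rows only, score held-out rows. Shared by CV,
# consensus evaluation and the experiment drivers.
train_and_score <- function(train, test, config, structure = NULL) {
  g <- if (is.null(structure)) learn_network(train, config) else structure
  net <- fit_parameters(g, train, config$prior)
  pos <- positive_state(train)
  pred <- predict_dataset(net, test)
  list(scores = pred$posterior[, pos],
       labels = as.integer(test$df[[test$phenotype]] == pos),
       structure = g, net = net)
}

#' Stratified k-fold cross-validation
#'
#' Splits rows into seeded stratified folds; for each fold the network
#' structure and parameters are learned on the training portion only and the
#' held-out rows are scored by the posterior probability of the positive
#' phenotype state. Reported are the per-fold AUCs and the pooled AUC over
#' the concatenated held-out scores (more stable at small n). With
#' `tune = TRUE` a grid of prior hyperparameters is searched by pooled CV
#' AUC (ties resolved toward smaller `alpha`, then smaller `nu`) and the
#' winning prior is refitted and reported.
#'
#' @param data a `mixed_data` object with a binary phenotype.
#' @param config a `search_config`.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param tune grid-search the prior hyperparameters.
#' @param alpha_grid,nu_grid tuning grids (defaults 0.5, 1, 2, 5, 10).
#' @param structure optional fixed `cgbn_dag`: when supplied, only the
#'   parameters are re-learned per fold (used by consensus-network
#'   evaluation).
#' @return An object of class `cgbn_cv`: `fold_auc`, `pooled_auc`, `fold`
#'   (assignment vector), `scores`, `labels`, `prior`, and when tuning the
#'   full `tuning_grid` results.
#' @export
cross_validate <- function(data, config = search_config(), folds = 5L,
                           seed = config$seed, tune = FALSE,
                           alpha_grid = c(0.5, 1, 2, 5, 10),
                           nu_grid = c(0.5, 1, 2, 5, 10),
                           structure = NULL) {
  pos <- positive_state(data)
  fold <- stratified_folds(data$df[[data$phenotype]], folds, seed)

  run_once <- function(config) {
    scores <- numeric(n_rows(data)); labels <- integer(n_rows(data))
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- subset_rows(data, which(fold != f))
      te <- subset_rows(data, which(fold == f))
      res <- train_and_score(tr, te, config, structure)
      scores[fold == f] <- res$scores
      labels[fold == f] <- res$labels
      fold_auc[f] <- if (length(unique(res$labels)) == 2L)
        roc_auc(res$scores, res$labels)$auc else NA_real_
    }
    list(scores = scores, labels = labels, fold_auc = fold_auc,
         pooled_auc = roc_auc(scores, labels)$auc)
  }

  tuning <- NULL
  if (tune) {
    grid <- expand.grid(alpha = alpha_grid, nu = nu_grid)
    grid$pooled_auc <- NA_real_
    for (i in seq_len(nrow(grid))) {
      cfg <- config
      cfg$prior <- prior_hyper(grid$alpha[i], grid$nu[i],
                               config$prior$sigma0_sq, config$prior$max_parents)
      grid$pooled_auc[i] <- run_once(cfg)$pooled_auc
    }
    best <- grid[order(-grid$pooled_auc, grid$alpha, grid$nu)[1L], ]
    config$prior <- prior_hyper(best$alpha, best$nu, config$prior$sigma0_sq,
                                config$prior$max_parents)
    tuning <- grid
  }
  res <- run_once(config)
  structure(list(fold_auc = res$fold_auc, pooled_auc = res$pooled_auc,
                 fold = fold, scores = res$scores, labels = res$labels,
                 prior = config$prior, positive = pos, tuning_grid = tuning),
            class = "cgbn_cv")
}

#' @export
print.cgbn_cv <- function(x, ...) {
  cat(sprintf("Cross-validation: pooled AUC %.4f (folds: %s)\n",
              x$pooled_auc, paste(sprintf("%.3f", x$fold_auc), collapse = " ")))
  invisible(x)
}
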