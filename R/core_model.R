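# Core data model: mixed datasets, DAG structures, conditional Gaussian
# network constraints, Markov blankets and parent-configuration indexing.

#' Construct a mixed discrete/continuous dataset
#'
#' Wraps a data frame of complete records together with per-column typing
#' (discrete or continuous), the state lists of the discrete columns and the
#' name of the designated phenotype column. Rows containing missing values are
#' dropped (complete-case contract) and the number of dropped rows is reported
#' via a message and stored in the `"n_dropped"` attribute.
#'
#' Column typing follows the convention of mixed-format statistical tables:
#' character and factor columns are discrete, numeric columns are continuous
#' unless overridden through `kinds`. Discrete state labels are taken in order
#' of first appearance unless an explicit state list is supplied, so that a
#' dataset read twice yields bit-identical parameter tables.
#'
#' @param x data frame of observations, one row per sample.
#' @param phenotype name of the (discrete) phenotype column.
#' @param kinds optional named character vector of `"discrete"` /
#'   `"continuous"` overrides, by column name.
#' @param states optional named list of state-label vectors for discrete
#'   columns (each a character vector of at least two unique labels; labels
#'   present in the data but absent from the supplied list are an error).
#' @return An object of class `mixed_data`: a list with elements `df`
#'   (data frame, discrete columns stored as character), `kinds`, `states`
#'   and `phenotype`.
#' @examples
#' d <- data.frame(pheno = c("ctrl", "case", "ctrl"), x = c(0.1, 2.3, -1))
#' md <- mixed_data(d, phenotype = "pheno")
#' md$kinds
#' @export
mixed_data <- function(x, phenotype, kinds = NULL, states = NULL) {
  stopifnot(is.data.frame(x), ncol(x) >= 1L)
  nm <- names(x)
  if (anyDuplicated(nm)) stop("duplicate column names in dataset")
  if (!phenotype %in% nm) stop("phenotype column '", phenotype, "' not found")

  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("mixed_data: dropped ", n_dropped, " incomplete row(s)")
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 1L) stop("no complete rows in dataset")
  rownames(x) <- NULL

  infer_kind <- function(col) {
    if (is.numeric(col)) "continuous" else "discrete"
  }
  k <- vapply(x, infer_kind, character(1))
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), nm)
    if (length(bad)) stop("kind override for unknown column: ", bad[1])
    if (!all(kinds %in% c("discrete", "continuous")))
      stop("kinds must be 'discrete' or 'continuous'")
    k[names(kinds)] <- kinds
  }
  if (k[[phenotype]] != "discrete")
    stop("phenotype column must be discrete")

  # coerce discrete columns to character, continuous to double
  for (j in nm) {
    if (k[[j]] == "discrete") {
      x[[j]] <- as.character(x[[j]])
    } else {
      if (!is.numeric(x[[j]]))
        stop("column '", j, "' declared continuous but is not numeric")
      x[[j]] <- as.double(x[[j]])
    }
  }

  st <- list()
  for (j in nm[k == "discrete"]) {
    observed <- unique(x[[j]])   # first-appearance order
    if (!is.null(states) && !is.null(states[[j]])) {
      sj <- as.character(states[[j]])
      if (anyDuplicated(sj)) stop("duplicate states for '", j, "'")
      extra <- setdiff(observed, sj)
      if (length(extra))
        stop("column '", j, "' contains state(s) not in supplied list: ",
             paste(extra, collapse = ", "))
      st[[j]] <- sj
    } else {
      st[[j]] <- observed
    }
  }

  out <- structure(
    list(df = x, kinds = k, states = st, phenotype = phenotype),
    class = "mixed_data")
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.mixed_data <- function(x, ...) {
  cat("Mixed dataset: ", nrow(x$df), " rows, ",
      sum(x$kinds == "discrete"), " discrete + ",
      sum(x$kinds == "continuous"), " continuous variables\n", sep = "")
  cat("Phenotype: ", x$phenotype, " (states: ",
      paste(x$states[[x$phenotype]], collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.mixed_data <- function(x) dim(x$df)

n_rows <- function(data) nrow(data$df)

var_names <- function(data) names(data$df)

is_discrete <- function(data, name) data$kinds[[name]] == "discrete"

#' Subset rows of a mixed dataset
#'
#' Keeps the typing, state lists and phenotype designation; used by the
#' cross-validation and bootstrap machinery. State lists are preserved even
#' when a state is absent from the subset, so parameter-table layouts stay
#' comparable across resamples.
#'
#' @param data a `mixed_data` object.
#' @param i integer row indices (duplicates allowed, as in bootstrap
#'   resampling).
#' @return A `mixed_data` object with the selected rows.
#' @export
subset_rows <- function(data, i) {
  stopifnot(inherits(data, "mixed_data"))
  df <- data$df[i, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(df = df, kinds = data$kinds, states = data$states,
                 phenotype = data$phenotype),
            class = "mixed_data")
}

#' Construct a directed network structure
#'
#' @param nodes character vector of node names (unique).
#' @param edges optional two-column character matrix or data frame of
#'   (parent, child) pairs.
#' @return An object of class `cgbn_dag`: list with `nodes` and `parents`
#'   (named list mapping each node to its parent names, kept sorted).
#' @examples
#' g <- dag(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
#' is_acyclic(g)
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  g <- structure(list(nodes = nodes, parents = parents), class = "cgbn_dag")
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.matrix(edges)
    for (r in seq_len(nrow(edges)))
      g <- add_edge(g, edges[r, 1L], edges[r, 2L])
  }
  g
}

#' @export
print.cgbn_dag <- function(x, ...) {
  em <- edge_matrix(x)
  cat("DAG: ", length(x$nodes), " nodes, ", nrow(em), " edges\n", sep = "")
  if (nrow(em))
    cat(paste0("  ", em[, 1L], " -> ", em[, 2L]), sep = "\n")
  invisible(x)
}

check_node <- function(structure, node) {
  if (!node %in% structure$nodes)
    stop("unknown node '", node, "'")
}

#' Add or remove a directed edge
#'
#' `add_edge` and `remove_edge` return a modified copy; neither checks
#' acyclicity (searches check legality before committing a move).
#'
#' @param structure a `cgbn_dag`.
#' @param parent,child node names.
#' @return The modified `cgbn_dag`.
#' @export
add_edge <- function(structure, parent, child) {
  check_node(structure, parent); check_node(structure, child)
  if (parent == child) stop("self-loop ", parent, " -> ", child)
  p <- structure$parents[[child]]
  if (!parent %in% p)
    structure$parents[[child]] <- sort(c(p, parent))
  structure
}

#' @rdname add_edge
#' @export
remove_edge <- function(structure, parent, child) {
  check_node(structure, parent); check_node(structure, child)
  structure$parents[[child]] <- setdiff(structure$parents[[child]], parent)
  structure
}

has_edge <- function(structure, parent, child) {
  parent %in% structure$parents[[child]]
}

#' Edge list of a structure
#'
#' @param structure a `cgbn_dag`.
#' @return Two-column character matrix with columns `parent`, `child`, in
#'   lexicographic (child, parent) order.
#' @export
edge_matrix <- function(structure) {
  ps <- structure$parents
  child <- rep(names(ps), lengths(ps))
  parent <- unlist(ps, use.names = FALSE)
  if (is.null(parent)) parent <- character(0)
  m <- cbind(parent = parent, child = child)
  m[order(m[, "child"], m[, "parent"]), , drop = FALSE]
}

n_edges <- function(structure) sum(lengths(structure$parents))

children_of <- function(structure, node) {
  ps <- structure$parents
  names(ps)[vapply(ps, function(p) node %in% p, logical(1))]
}

#' Test whether a structure is acyclic
#'
#' Depth-first search with the classic three-colour marking; iterative (own
#' stack) so deep chains cannot exhaust the C recursion limit.
#'
#' @param structure a `cgbn_dag`.
#' @return `TRUE` iff the directed graph has no cycle.
#' @export
is_acyclic <- function(structure) {
  nodes <- structure$nodes
  kids <- lapply(stats::setNames(nodes, nodes),
                 function(v) children_of(structure, v))
  for (p in unlist(structure$parents, use.names = FALSE))
    if (!p %in% nodes) stop("edge references undeclared node '", p, "'")
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 white 1 grey 2 black
  for (root in nodes) {
    if (color[[root]] != 0L) next
    stack <- list(list(node = root, next_child = 1L))
    color[[root]] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ch <- kids[[top$node]]
      if (top$next_child > length(ch)) {
        color[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
      } else {
        stack[[length(stack)]]$next_child <- top$next_child + 1L
        v <- ch[[top$next_child]]
        if (color[[v]] == 1L) return(FALSE)
        if (color[[v]] == 0L) {
          color[[v]] <- 1L
          stack[[length(stack) + 1L]] <- list(node = v, next_child = 1L)
        }
      }
    }
  }
  TRUE
}

# Would adding parent -> child create a directed cycle? True iff child
# already reaches parent. Used by the searches before committing a move.
creates_cycle <- function(structure, parent, child) {
  if (parent == child) return(TRUE)
  seen <- character(0)
  frontier <- child
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      ch <- children_of(structure, v)
      if (parent %in% ch) return(TRUE)
      nxt <- c(nxt, setdiff(ch, seen))
    }
    seen <- c(seen, frontier)
    frontier <- unique(setdiff(nxt, seen))
  }
  FALSE
}

#' Check the conditional Gaussian structural restriction
#'
#' In a conditional Gaussian network a discrete node may not depend on a
#' continuous node: every continuous-to-discrete edge is reported as a
#' violation. An empty result means the structure is a legal CGBN skeleton.
#'
#' @param structure a `cgbn_dag`.
#' @param kinds named character vector mapping node names to
#'   `"discrete"`/`"continuous"` (a `mixed_data` object is also accepted).
#' @return Character vector of violating edges formatted `"parent->child"`
#'   (empty when legal).
#' @export
validate_cg_constraints <- function(structure, kinds) {
  if (inherits(kinds, "mixed_data")) kinds <- kinds$kinds
  miss <- setdiff(structure$nodes, names(kinds))
  if (length(miss)) stop("no kind declared for node '", miss[1], "'")
  out <- character(0)
  for (child in structure$nodes) {
    if (kinds[[child]] != "discrete") next
    bad <- structure$parents[[child]][
      kinds[structure$parents[[child]]] == "continuous"]
    if (length(bad)) out <- c(out, paste0(bad, "->", child))
  }
  sort(out)
}

#' Markov blanket of a node
#'
#' Parents, children and the children's other parents; conditioning on the
#' blanket renders the node independent of the remaining variables, which is
#' what makes blanket-restricted phenotype prediction exact.
#'
#' @param structure a `cgbn_dag`.
#' @param node node name.
#' @return Character vector of blanket member names (sorted, excludes
#'   `node`).
#' @export
markov_blanket <- function(structure, node) {
  check_node(structure, node)
  kids <- children_of(structure, node)
  coparents <- unlist(lapply(kids, function(c) structure$parents[[c]]),
                      use.names = FALSE)
  sort(setdiff(unique(c(structure$parents[[node]], kids, coparents)), node))
}

#' Enumerate discrete-parent configurations of a node
#'
#' Configurations are laid out row-major over the discrete parents sorted by
#' name (the first parent varies slowest), each parent's states in declared
#' order. This fixed convention indexes every CPT row and every conditional
#' linear Gaussian parameter set in the package, so serialized parameter
#' tables are stable across runs.
#'
#' @param structure a `cgbn_dag`.
#' @param node node name.
#' @param data a `mixed_data` object (or a list with `kinds` and `states`)
#'   supplying state lists.
#' @return Data frame with one column per discrete parent (sorted by name)
#'   and one row per configuration; a single zero-column row when the node
#'   has no discrete parents.
#' @export
parent_configurations <- function(structure, node, data) {
  check_node(structure, node)
  dp <- discrete_parents(structure, node, data)
  if (!length(dp)) {
    df <- as.data.frame(matrix(nrow = 1L, ncol = 0L))
    return(df)
  }
  # expand.grid varies the FIRST factor fastest; feed reversed parents so the
  # first (alphabetically) parent varies slowest, then restore column order.
  grid <- expand.grid(rev(lapply(dp, function(p) data$states[[p]])),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- rev(dp)
  grid <- grid[, dp, drop = FALSE]
  rownames(grid) <- NULL
  grid
}

discrete_parents <- function(structure, node, data) {
  p <- structure$parents[[node]]
  sort(p[vapply(p, function(v) data$kinds[[v]] == "discrete", logical(1))])
}

continuous_parents <- function(structure, node, data) {
  p <- structure$parents[[node]]
  sort(p[vapply(p, function(v) data$kinds[[v]] == "continuous", logical(1))])
}

# Row-major configuration index (1-based) of each data row for `node`'s
# discrete parents. Returns a vector of 1s when there are none. Also used to
# index CPT rows at prediction time via per-variable state assignments.
config_index_of <- function(structure, node, data, assign = NULL) {
  dp <- discrete_parents(structure, node, data)
  n <- if (is.null(assign)) n_rows(data) else 1L
  if (!length(dp)) return(rep(1L, n))
  idx <- rep(1L, n)
  for (p in dp) {
    st <- data$states[[p]]
    val <- if (is.null(assign)) data$df[[p]] else assign[[p]]
    pos <- match(val, st)
    if (anyNA(pos))
      stop("value of '", p, "' outside declared states")
    idx <- (idx - 1L) * length(st) + pos
  }
  idx
}

n_configs <- function(structure, node, data) {
  dp <- discrete_parents(structure, node, data)
  if (!length(dp)) return(1L)
  prod(vapply(dp, function(p) length(data$states[[p]]), integer(1)))
}

# Topological order of the DAG (Kahn); error if cyclic.
topo_order <- function(structure) {
  indeg <- vapply(structure$parents, length, integer(1))
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  while (length(avail)) {
    v <- avail[[1L]]; avail <- avail[-1L]
    order <- c(order, v)
    for (c in children_of(structure, v)) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) avail <- sort(c(avail, c))
    }
  }
  if (length(order) != length(structure$nodes)) stop("graph is cyclic")
  order
}

#' Assemble a conditional Gaussian network from explicit parameters
#'
#' Low-level constructor used by the simulator and by tests that need
#' networks with exactly specified parameters; [fit_parameters()] is the
#' data-driven route. Parameter tables are validated against the structure:
#' CPT rows must match the row-major discrete-parent configuration layout of
#' [parent_configurations()] and sum to one, conditional Gaussian tables must
#' carry one coefficient per continuous parent and positive variances.
#'
#' @param structure a `cgbn_dag`.
#' @param params named list: for each discrete node `list(kind="discrete",
#'   cpt=<q x r matrix>)`; for each continuous node
#'   `list(kind="continuous", cont_parents=<chr>, beta=<q x (1+p) matrix>,
#'   sigma2=<length-q vector>)`.
#' @param kinds named character vector of node kinds.
#' @param states named list of state labels for the discrete nodes.
#' @param phenotype designated discrete phenotype node.
#' @param prior optional `prior_hyper` to record.
#' @return An object of class `cgbn`.
#' @export
cgbn <- function(structure, params, kinds, states, phenotype,
                 prior = prior_hyper()) {
  stopifnot(inherits(structure, "cgbn_dag"))
  viol <- validate_cg_constraints(structure, kinds)
  if (length(viol)) stop("illegal CG structure: ", paste(viol, collapse = ", "))
  if (!is_acyclic(structure)) stop("structure is cyclic")
  if (!phenotype %in% structure$nodes || kinds[[phenotype]] != "discrete")
    stop("phenotype must be a discrete node")
  spec <- list(kinds = kinds, states = states)
  for (v in structure$nodes) {
    pr <- params[[v]]
    if (is.null(pr)) stop("missing parameters for node '", v, "'")
    q <- {
      dp <- sort(structure$parents[[v]][kinds[structure$parents[[v]]] == "discrete"])
      if (length(dp)) prod(vapply(dp, function(p) length(states[[p]]), integer(1))) else 1L
    }
    if (kinds[[v]] == "discrete") {
      if (pr$kind != "discrete" || !is.matrix(pr$cpt) ||
          nrow(pr$cpt) != q || ncol(pr$cpt) != length(states[[v]]))
        stop("bad CPT shape for node '", v, "'")
      if (any(pr$cpt < 0) || any(abs(rowSums(pr$cpt) - 1) > 1e-12))
        stop("CPT rows of '", v, "' must be non-negative and sum to 1")
      colnames(params[[v]]$cpt) <- states[[v]]
    } else {
      cp <- sort(pr$cont_parents)
      expected <- sort(structure$parents[[v]][kinds[structure$parents[[v]]] == "continuous"])
      if (!identical(cp, expected))
        stop("cont_parents of '", v, "' disagree with the structure")
      if (!is.matrix(pr$beta) || nrow(pr$beta) != q ||
          ncol(pr$beta) != 1L + length(cp))
        stop("bad coefficient shape for node '", v, "'")
      if (length(pr$sigma2) != q || any(pr$sigma2 <= 0))
        stop("variances of '", v, "' must be positive, one per configuration")
      params[[v]]$cont_parents <- cp
      colnames(params[[v]]$beta) <- c("(intercept)", cp)
    }
  }
  structure(list(structure = structure, params = params, kinds = kinds,
                 states = states, phenotype = phenotype, prior = prior),
            class = "cgbn")
}
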