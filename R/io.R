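# Readers and writers: delimited mixed tables, PED genotype files, network
# exchange formats (TGF, SIF, GraphML) and a native JSON serialization that
# round-trips structures together with their fitted parameters.

#' Read a delimited mixed table
#'
#' Reads a header-bearing delimited text file into a [mixed_data()] object.
#' Columns whose every non-missing token parses as a number become
#' continuous, any other column becomes discrete; `kinds` overrides win.
#' Empty fields and `NA` tokens are missing values; rows containing any are
#' dropped with a message (complete-case contract). All-numeric columns with
#' few distinct values are flagged in a message as possibly discrete codes.
#'
#' @param path file path.
#' @param phenotype name of the phenotype column (must be discrete after
#'   typing/overrides).
#' @param delimiter field delimiter (default comma).
#' @param kinds optional named character vector of type overrides.
#' @return A `mixed_data` object.
#' @export
read_mixed_table <- function(path, phenotype, delimiter = ",", kinds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "\"",
                           comment.char = "")
  if (!nrow(raw)) stop("empty table: ", path)
  is_num <- function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(FALSE)
    !anyNA(suppressWarnings(as.numeric(col[ok])))
  }
  for (j in names(raw)) {
    override <- !is.null(kinds) && !is.na(kinds[j]) && j %in% names(kinds)
    if (is_num(raw[[j]]) && !(override && kinds[[j]] == "discrete")) {
      vals <- suppressWarnings(as.numeric(raw[[j]]))
      nu <- length(unique(vals[!is.na(vals)]))
      if (nu <= 10L && all(vals[!is.na(vals)] == round(vals[!is.na(vals)])))
        message("read_mixed_table: column '", j, "' is integer-coded with ",
                nu, " distinct values; possibly discrete (override with kinds=)")
      raw[[j]] <- vals
    }
  }
  mixed_data(raw, phenotype = phenotype, kinds = kinds)
}

#' Write a mixed table
#'
#' Delimited text with header; continuous values are printed with 17
#' significant digits so that a write/read round trip is bit-exact.
#'
#' @param data a `mixed_data` object.
#' @param path output path.
#' @param delimiter field delimiter.
#' @return `path`, invisibly.
#' @export
write_mixed_table <- function(data, path, delimiter = ",") {
  df <- data$df
  for (v in names(df))
    if (data$kinds[[v]] == "continuous")
      df[[v]] <- sprintf("%.17g", df[[v]])
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a PED genotype file
#'
#' Canonical whitespace-delimited PED dialect: six leading columns (family,
#' individual, paternal and maternal IDs, sex, phenotype) followed by one
#' allele pair per SNP. Each SNP becomes a discrete variable whose genotype
#' state is the sorted allele pair (so `G A` and `A G` are the same state
#' `"AG"`); the missing-allele code `0` makes the genotype (and hence the
#' row) missing, and PED phenotype codes 1/2 map to `"control"`/`"case"`
#' (anything else is missing). Incomplete rows are dropped with a message.
#'
#' @param ped_path PED file path.
#' @param map_path optional MAP file supplying SNP names (second column);
#'   otherwise SNPs are named `SNP1`, `SNP2`, ...
#' @return A `mixed_data` with discrete SNP variables and phenotype
#'   `"pheno"`.
#' @export
read_ped <- function(ped_path, map_path = NULL) {
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty PED file: ", ped_path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (length(unique(len)) != 1L)
    stop("ragged PED file: line ", which(len != len[1L])[1L],
         " has ", len[len != len[1L]][1L], " fields, expected ", len[1L])
  if (len[1L] < 8L || (len[1L] - 6L) %% 2L != 0L)
    stop("PED line must have 6 leading columns plus allele pairs (odd allele count)")
  n_snp <- (len[1L] - 6L) %/% 2L
  snp_names <- if (!is.null(map_path)) {
    m <- utils::read.table(map_path, header = FALSE, colClasses = "character")
    if (nrow(m) != n_snp) stop("MAP file rows do not match SNP count")
    m[[2L]]
  } else paste0("SNP", seq_len(n_snp))

  mat <- do.call(rbind, toks)
  pheno <- ifelse(mat[, 6L] == "1", "control",
                  ifelse(mat[, 6L] == "2", "case", NA_character_))
  df <- data.frame(pheno = pheno, stringsAsFactors = FALSE)
  for (s in seq_len(n_snp)) {
    a1 <- mat[, 5L + 2L * s]
    a2 <- mat[, 6L + 2L * s]
    g <- ifelse(a1 == "0" | a2 == "0", NA_character_,
                paste0(pmin(a1, a2), pmax(a1, a2)))
    df[[snp_names[s]]] <- g
  }
  mixed_data(df, phenotype = "pheno")
}

#' Export a network structure to TGF, SIF or GraphML
#'
#' TGF: numbered node list, a `#` separator, then edge pairs. SIF:
#' `parent dep child` lines (isolated nodes on their own line). GraphML: a
#' directed graph with a `kind` node attribute carrying the
#' discrete/continuous typing when known. These exchange formats carry
#' structure only, not parameters; use [write_cgbn_json()] for a full
#' round trip.
#'
#' @param x a `cgbn_dag` or a fitted `cgbn`.
#' @param path output path.
#' @param format `"tgf"`, `"sif"` or `"graphml"`.
#' @param kinds optional named kind vector for the GraphML attribute
#'   (taken from `x` when it is a `cgbn`).
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path, format = c("tgf", "sif", "graphml"),
                          kinds = NULL) {
  format <- match.arg(format)
  if (inherits(x, "cgbn")) {
    if (is.null(kinds)) kinds <- x$kinds
    x <- x$structure
  }
  stopifnot(inherits(x, "cgbn_dag"))
  em <- edge_matrix(x)
  lines <- switch(format,
    tgf = {
      id <- stats::setNames(seq_along(x$nodes), x$nodes)
      c(paste(id, x$nodes), "#",
        if (nrow(em)) paste(id[em[, 1L]], id[em[, 2L]]))
    },
    sif = {
      isolated <- setdiff(x$nodes, unique(c(em)))
      c(if (nrow(em)) paste(em[, 1L], "dep", em[, 2L]), isolated)
    },
    graphml = {
      esc <- function(s) {
        s <- gsub("&", "&amp;", s, fixed = TRUE)
        s <- gsub("<", "&lt;", s, fixed = TRUE)
        gsub(">", "&gt;", s, fixed = TRUE)
      }
      node_lines <- vapply(x$nodes, function(v) {
        k <- if (!is.null(kinds) && v %in% names(kinds))
          sprintf("<data key=\"kind\">%s</data>", kinds[[v]]) else ""
        sprintf("    <node id=\"%s\">%s</node>", esc(v), k)
      }, character(1))
      edge_lines <- if (nrow(em)) sprintf(
        "    <edge source=\"%s\" target=\"%s\"/>",
        esc(em[, 1L]), esc(em[, 2L])) else character(0)
      c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
        "  <key id=\"kind\" for=\"node\" attr.name=\"kind\" attr.type=\"string\"/>",
        "  <graph id=\"G\" edgedefault=\"directed\">",
        node_lines, edge_lines,
        "  </graph>", "</graphml>")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore a fitted network as JSON
#'
#' The native serialization: structure, variable typing and state lists,
#' every parameter table and the prior, written with full numeric precision
#' so that a restored network reproduces identical posteriors.
#'
#' @param net a fitted `cgbn`.
#' @param path JSON file path.
#' @return `write_cgbn_json`: `path` invisibly; `read_cgbn_json`: the
#'   restored `cgbn`.
#' @export
write_cgbn_json <- function(net, path) {
  stopifnot(inherits(net, "cgbn"))
  obj <- list(
    format = "cgbn-network",
    version = 1L,
    phenotype = net$phenotype,
    nodes = net$structure$nodes,
    kinds = as.list(net$kinds),
    states = net$states,
    edges = {
      em <- edge_matrix(net$structure)
      if (nrow(em)) lapply(seq_len(nrow(em)),
                           function(r) list(parent = em[r, 1L],
                                            child = em[r, 2L]))
      else list()
    },
    prior = unclass(net$prior),
    params = lapply(net$structure$nodes, function(v) {
      pr <- net$params[[v]]
      row_list <- function(m) lapply(seq_len(nrow(m)),
                                     function(i) as.numeric(m[i, ]))
      if (pr$kind == "discrete")
        list(kind = "discrete", cpt = row_list(pr$cpt))
      else
        list(kind = "continuous", cont_parents = as.list(pr$cont_parents),
             beta = row_list(pr$beta), sigma2 = as.list(pr$sigma2))
    })
  )
  names(obj$params) <- net$structure$nodes
  # digits = I(17): significant digits, enough for an exact double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cgbn_json
#' @export
read_cgbn_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "cgbn-network"))
    stop("not a cgbn network JSON file: ", path)
  nodes <- unlist(obj$nodes)
  em <- if (length(obj$edges))
    cbind(vapply(obj$edges, `[[`, "", "parent"),
          vapply(obj$edges, `[[`, "", "child"))
  else NULL
  g <- dag(nodes, em)
  kinds <- unlist(obj$kinds)
  states <- lapply(obj$states, function(s) unlist(s))
  params <- lapply(stats::setNames(nodes, nodes), function(v) {
    pr <- obj$params[[v]]
    if (pr$kind == "discrete") {
      cpt <- do.call(rbind, lapply(pr$cpt, function(row) unlist(row)))
      list(kind = "discrete", cpt = matrix(as.numeric(cpt), nrow = nrow(cpt)))
    } else {
      beta <- do.call(rbind, lapply(pr$beta, function(row) unlist(row)))
      list(kind = "continuous",
           cont_parents = as.character(unlist(pr$cont_parents)),
           beta = matrix(as.numeric(beta), nrow = nrow(beta)),
           sigma2 = as.numeric(unlist(pr$sigma2)))
    }
  })
  prior <- prior_hyper(obj$prior$alpha, obj$prior$nu, obj$prior$sigma0_sq,
                       obj$prior$max_parents)
  cgbn(g, params, kinds, states, phenotype = obj$phenotype, prior = prior)
}
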