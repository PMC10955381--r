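#' Causal directed acyclic graphs
#'
#' A `causal_dag` is a small labelled DAG: a node set, a set of directed
#' edges, and an optional subset of nodes flagged as latent (unobserved).
#' It is the substrate for the identification checks ([d_separated()],
#' [backdoor_valid()], [enumerate_minimal_adjustment_sets()]) that mechanize
#' the study design's adjustment-set reasoning.
#'
#' @param edges two-column character matrix or data.frame, one row per
#'   directed edge `parent -> child`.
#' @param latent character vector of node names flagged as unobserved.
#' @param nodes optional extra (possibly isolated) node names.
#'
#' @return An object of class `causal_dag` with elements `nodes`, `edges`
#'   (two-column character matrix with columns `from`, `to`) and `latent`.
#' @examples
#' g <- causal_dag(rbind(c("A", "B"), c("B", "C")))
#' d_separated(g, "A", "C", "B")
#' @export
causal_dag <- function(edges, latent = character(), nodes = character()) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    stop("`edges` must be a two-column matrix (from, to)", call. = FALSE)
  }
  storage.mode(edges) <- "character"
  colnames(edges) <- c("from", "to")
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) {
    edges <- edges[!duplicated(paste(edges[, 1L], edges[, 2L])), , drop = FALSE]
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (!all(latent %in% nodes)) {
    stop("latent nodes must be members of the node set", call. = FALSE)
  }
  dag <- structure(
    list(nodes = nodes, edges = edges, latent = sort(unique(latent))),
    class = "causal_dag"
  )
  if (is.null(topological_order(dag))) {
    stop("edge set contains a directed cycle", call. = FALSE)
  }
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("causal_dag:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat(paste0("  ", x$edges[, 1L], " -> ", x$edges[, 2L], collapse = "\n"), "\n")
  }
  if (length(x$latent)) cat("  latent:", paste(x$latent, collapse = ", "), "\n")
  invisible(x)
}

# Kahn's algorithm; NULL when a cycle exists.
topological_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(dag$edges))) {
    indeg[dag$edges[i, 2L]] <- indeg[dag$edges[i, 2L]] + 1L
  }
  order <- character(0)
  queue <- names(indeg)[indeg == 0L]
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    ch <- dag$edges[dag$edges[, 1L] == v, 2L]
    for (c in ch) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

check_nodes <- function(dag, x) {
  bad <- setdiff(x, dag$nodes)
  if (length(bad)) {
    stop("unknown node name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

dag_parents <- function(dag, v) dag$edges[dag$edges[, 2L] == v, 1L]
dag_children <- function(dag, v) dag$edges[dag$edges[, 1L] == v, 2L]

#' Descendants of a node
#'
#' All nodes reachable from `v` by a directed path, excluding `v` itself.
#'
#' @param dag a [causal_dag()].
#' @param v node name.
#' @return Character vector of descendant node names.
#' @export
dag_descendants <- function(dag, v) {
  check_nodes(dag, v)
  seen <- character(0)
  frontier <- dag_children(dag, v)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unlist(lapply(frontier, dag_children, dag = dag)), seen)
  }
  sort(setdiff(seen, v))
}

# All simple undirected paths from x to y: list of node vectors.
all_undirected_paths <- function(dag, x, y) {
  nbr <- lapply(stats::setNames(dag$nodes, dag$nodes), function(v) {
    union(dag_parents(dag, v), dag_children(dag, v))
  })
  paths <- list()
  walk <- function(path) {
    v <- path[[length(path)]]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in setdiff(nbr[[v]], path)) walk(c(path, w))
  }
  walk(x)
  paths
}

# Is this undirected path blocked by z under d-separation rules?
path_blocked <- function(dag, path, z) {
  if (length(path) <= 2L) return(FALSE)
  for (i in 2L:(length(path) - 1L)) {
    a <- path[[i - 1L]]; v <- path[[i]]; b <- path[[i + 1L]]
    into_v_left <- any(dag$edges[, 1L] == a & dag$edges[, 2L] == v)
    into_v_right <- any(dag$edges[, 1L] == b & dag$edges[, 2L] == v)
    collider <- into_v_left && into_v_right
    if (collider) {
      opened <- v %in% z || length(intersect(dag_descendants(dag, v), z)) > 0L
      if (!opened) return(TRUE)
    } else {
      if (v %in% z) return(TRUE)
    }
  }
  FALSE
}

#' d-separation by explicit path enumeration
#'
#' `x` and `y` are d-separated given `z` when every undirected path between
#' them is blocked: a chain or fork is blocked when its middle node is in
#' `z`; a collider blocks unless it, or one of its descendants, is in `z`.
#' Graphs here are small, so paths are enumerated explicitly.
#'
#' @param dag a [causal_dag()].
#' @param x,y node names.
#' @param z character vector of conditioning nodes (may be empty).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @seealso [d_separated_moral()] for the independent moralization-based
#'   check used to validate this one.
#' @export
d_separated <- function(dag, x, y, z = character()) {
  check_nodes(dag, c(x, y, z))
  if (x == y) stop("x and y must differ", call. = FALSE)
  if (x %in% z || y %in% z) stop("z must exclude x and y", call. = FALSE)
  paths <- all_undirected_paths(dag, x, y)
  all(vapply(paths, path_blocked, logical(1), dag = dag, z = z))
}

#' d-separation via moralization (independent oracle)
#'
#' Classic alternative route: restrict to the ancestral graph of
#' `{x, y} U z`, moralize (marry parents of a common child, drop
#' directions), delete `z`, and test undirected connectivity of `x` and
#' `y`. Kept deliberately independent of [d_separated()] so the two can
#' cross-check each other.
#'
#' @inheritParams d_separated
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @export
d_separated_moral <- function(dag, x, y, z = character()) {
  check_nodes(dag, c(x, y, z))
  if (x == y) stop("x and y must differ", call. = FALSE)
  if (x %in% z || y %in% z) stop("z must exclude x and y", call. = FALSE)
  # ancestors of the query set, inclusive
  anc <- keep <- unique(c(x, y, z))
  frontier <- anc
  while (length(frontier)) {
    ps <- setdiff(unlist(lapply(frontier, dag_parents, dag = dag)), keep)
    keep <- union(keep, ps)
    frontier <- ps
  }
  sub <- dag$edges[dag$edges[, 1L] %in% keep & dag$edges[, 2L] %in% keep, ,
                   drop = FALSE]
  # undirected adjacency with moral edges
  adj <- lapply(stats::setNames(keep, keep), function(v) character(0))
  link <- function(a, b) {
    adj[[a]] <<- union(adj[[a]], b)
    adj[[b]] <<- union(adj[[b]], a)
  }
  for (i in seq_len(nrow(sub))) link(sub[i, 1L], sub[i, 2L])
  for (v in keep) {
    ps <- sub[sub[, 2L] == v, 1L]
    if (length(ps) > 1L) {
      prs <- utils::combn(ps, 2L)
      for (j in seq_len(ncol(prs))) link(prs[1L, j], prs[2L, j])
    }
  }
  # remove z, then BFS
  live <- setdiff(keep, z)
  frontier <- x; seen <- x
  while (length(frontier)) {
    nxt <- setdiff(intersect(unlist(adj[frontier]), live), seen)
    if (y %in% nxt) return(FALSE)
    seen <- union(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

#' Backdoor criterion check
#'
#' Tests whether a conditioning set satisfies Pearl's backdoor criterion
#' for the effect of `exposure` on `outcome`: no member of the set is a
#' descendant of the exposure, and the set d-separates exposure from
#' outcome in the graph with the exposure's outgoing edges removed (so
#' only backdoor paths — those entering the exposure — remain).
#'
#' @param dag a [causal_dag()].
#' @param exposure,outcome node names.
#' @param z conditioning set (character vector, may be empty). Latent
#'   nodes are not permitted: they cannot be conditioned on.
#' @return `TRUE` when the set is a valid backdoor adjustment set.
#' @export
backdoor_valid <- function(dag, exposure, outcome, z = character()) {
  check_nodes(dag, c(exposure, outcome, z))
  if (exposure == outcome) stop("exposure and outcome must differ", call. = FALSE)
  if (exposure %in% z || outcome %in% z) {
    stop("conditioning set must exclude exposure and outcome", call. = FALSE)
  }
  if (length(intersect(z, dag$latent))) {
    stop("conditioning set contains latent node(s): ",
         paste(intersect(z, dag$latent), collapse = ", "), call. = FALSE)
  }
  if (length(intersect(z, dag_descendants(dag, exposure)))) return(FALSE)
  keep <- dag$edges[, 1L] != exposure
  gx <- causal_dag(dag$edges[keep, , drop = FALSE], latent = dag$latent,
                   nodes = dag$nodes)
  d_separated(gx, exposure, outcome, z)
}

#' Enumerate minimal backdoor adjustment sets
#'
#' Brute-force search over subsets of observed non-descendants of the
#' exposure, returning every valid set that has no valid proper subset,
#' sorted by size then lexicographically.
#'
#' @inheritParams backdoor_valid
#' @return A list of character vectors (possibly containing the empty set).
#' @export
enumerate_minimal_adjustment_sets <- function(dag, exposure, outcome) {
  check_nodes(dag, c(exposure, outcome))
  if (exposure == outcome) stop("exposure and outcome must differ", call. = FALSE)
  cand <- setdiff(dag$nodes,
                  c(exposure, outcome, dag$latent, dag_descendants(dag, exposure)))
  cand <- sort(cand)
  subsets <- list(character(0))
  for (v in cand) subsets <- c(subsets, lapply(subsets, c, v))
  valid <- Filter(function(s) backdoor_valid(dag, exposure, outcome, s), subsets)
  keyset <- vapply(valid, function(s) paste(sort(s), collapse = "\r"), character(1))
  is_min <- vapply(seq_along(valid), function(i) {
    s <- valid[[i]]
    !any(vapply(seq_along(valid), function(j) {
      j != i && length(valid[[j]]) < length(s) && all(valid[[j]] %in% s)
    }, logical(1)))
  }, logical(1))
  out <- valid[is_min]
  out <- out[!duplicated(keyset[is_min])]
  ord <- order(lengths(out),
               vapply(out, function(s) paste(sort(s), collapse = " "), character(1)))
  lapply(out[ord], sort)
}

#' The study's causal DAG
#'
#' Builds the default causal model for the cross-site survey: sex and age
#' confound education, food insecurity and religiosity; education affects
#' number of children, food insecurity and religiosity; children affect
#' food insecurity and religiosity; food insecurity affects religiosity.
#' Optionally adds a latent `EducationType` node affecting religiosity,
#' and (second flag) also food insecurity — the unmeasured-confounder
#' scenario under which the observed adjustment set stops being valid.
#'
#' The DAG is data, not code: see [read_dag()] to load alternative edge
#' lists from plain text.
#'
#' @param include_education_type add the latent `EducationType` node with
#'   an edge into `Religiosity`.
#' @param education_type_causes_food_security additionally add
#'   `EducationType -> FoodInsecurity` (requires the first flag).
#' @return A [causal_dag()].
#' @export
build_study_dag <- function(include_education_type = FALSE,
                            education_type_causes_food_security = FALSE) {
  edges <- rbind(
    c("Sex", "Education"),
    c("Age", "Education"),
    c("Sex", "Religiosity"),
    c("Age", "Religiosity"),
    c("Sex", "FoodInsecurity"),
    c("Age", "FoodInsecurity"),
    c("Education", "Children"),
    c("Children", "FoodInsecurity"),
    c("Children", "Religiosity"),
    c("Education", "FoodInsecurity"),
    c("Education", "Religiosity"),
    c("FoodInsecurity", "Religiosity")
  )
  latent <- character(0)
  if (include_education_type) {
    edges <- rbind(edges, c("EducationType", "Religiosity"))
    if (education_type_causes_food_security) {
      edges <- rbind(edges, c("EducationType", "FoodInsecurity"))
    }
    latent <- "EducationType"
  } else if (education_type_causes_food_security) {
    stop("education_type_causes_food_security requires include_education_type",
         call. = FALSE)
  }
  causal_dag(edges, latent = latent)
}

#' Read / write a DAG as a plain-text edge list
#'
#' Format: one `parent -> child` per line; an optional header line
#' `# latent: A B` lists unobserved nodes; blank lines and other `#`
#' comments are ignored.
#'
#' @param path file path.
#' @return `read_dag()` returns a [causal_dag()]; `write_dag()` returns
#'   `path` invisibly.
#' @export
read_dag <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  latent <- character(0)
  lat <- grepl("^#\\s*latent:", lines)
  if (any(lat)) {
    latent <- unlist(strsplit(trimws(sub("^#\\s*latent:", "", lines[lat])), "\\s+"))
  }
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\\s*->\\s*")
  if (any(lengths(parts) != 2L)) {
    stop("each edge line must be of the form 'parent -> child'", call. = FALSE)
  }
  causal_dag(do.call(rbind, parts), latent = latent)
}

#' @rdname read_dag
#' @param dag a [causal_dag()].
#' @export
write_dag <- function(dag, path) {
  lines <- character(0)
  if (length(dag$latent)) {
    lines <- paste("# latent:", paste(dag$latent, collapse = " "))
  }
  lines <- c(lines, paste(dag$edges[, 1L], "->", dag$edges[, 2L]))
  writeLines(lines, path)
  invisible(path)
}
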