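## Mixed-mark graphs (MAGs and PAGs): endpoint-mark representation and basic
## accessors.  The mark table `amat` is a square integer matrix with
## amat[i, j] = mark at the j end of the edge i - j, using the coding
## 0 = absent, 1 = circle, 2 = arrowhead, 3 = tail.  Absence must be
## symmetric (no half-edges); everything else is free per graph class.

#' Endpoint mark codes
#'
#' Integer codes used in the mark table of a [marked_graph()]:
#' `0` absent, `1` circle (non-invariant mark), `2` arrowhead
#' (non-ancestral), `3` tail (ancestral).
#'
#' @format A named integer vector of length 4.
#' @export
MARKS <- c(absent = 0L, circle = 1L, arrowhead = 2L, tail = 3L)

MARK_ABSENT <- 0L
MARK_CIRCLE <- 1L
MARK_ARROW  <- 2L
MARK_TAIL   <- 3L

#' Construct a mixed-mark graph
#'
#' A marked graph stores, for every ordered pair of nodes, the edge mark at
#' the second node of the pair.  Maximal ancestral graphs (MAGs) use only
#' arrowheads and tails; partial ancestral graphs (PAGs) additionally use
#' circles for non-invariant marks.
#'
#' @param labels Character vector of unique node labels.
#' @param amat Optional integer matrix of endpoint marks, `amat[i, j]` being
#'   the mark at `j` on the edge `i - j` (codes in [MARKS]).  Defaults to the
#'   empty graph.
#' @return An object of class `marked_graph`.
#' @seealso [add_edge()], [graph_from_edges()], [is_valid_ancestral()]
#' @export
marked_graph <- function(labels, amat = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("node labels must be unique")
  p <- length(labels)
  if (is.null(amat)) {
    amat <- matrix(MARK_ABSENT, p, p, dimnames = list(labels, labels))
  } else {
    amat <- as.matrix(amat)
    storage.mode(amat) <- "integer"
    if (nrow(amat) != p || ncol(amat) != p)
      stop("mark table dimensions do not match the number of labels")
    dimnames(amat) <- list(labels, labels)
  }
  g <- structure(list(labels = labels, amat = amat), class = "marked_graph")
  validate_marked_graph(g)
  g
}

validate_marked_graph <- function(g) {
  a <- g$amat
  if (!all(a %in% 0:3)) stop("invalid mark code in mark table")
  if (any(diag(a) != MARK_ABSENT)) stop("self-marks must be absent")
  bad <- (a == MARK_ABSENT) != (t(a) == MARK_ABSENT)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("half-edge between '%s' and '%s': absence must be symmetric",
                 g$labels[idx[1]], g$labels[idx[2]]))
  }
  invisible(g)
}

node_index <- function(g, x) {
  i <- match(x, g$labels)
  if (anyNA(i)) stop(sprintf("unknown node label: '%s'", x[which(is.na(i))[1]]))
  i
}

#' Add or replace an edge in a marked graph
#'
#' @param g A [marked_graph()].
#' @param x,y Node labels.
#' @param mark_x Mark at the `x` endpoint (name in [MARKS] or integer code).
#' @param mark_y Mark at the `y` endpoint.
#' @return A new `marked_graph`; `g` is not modified.
#' @export
add_edge <- function(g, x, y, mark_x, mark_y) {
  i <- node_index(g, x); j <- node_index(g, y)
  if (i == j) stop("self-loops are not allowed")
  mx <- resolve_mark(mark_x); my <- resolve_mark(mark_y)
  if ((mx == MARK_ABSENT) != (my == MARK_ABSENT))
    stop("an edge is either present (two marks) or absent at both ends")
  g$amat[j, i] <- mx   # mark at x on edge y - x
  g$amat[i, j] <- my   # mark at y on edge x - y
  g
}

resolve_mark <- function(m) {
  if (is.character(m)) {
    code <- MARKS[match(m, names(MARKS))]
    if (anyNA(code)) stop(sprintf("unknown mark name '%s'", m))
    return(unname(code))
  }
  m <- as.integer(m)
  if (!m %in% 0:3) stop("mark code must be in 0:3")
  m
}

#' Build a marked graph from an edge list
#'
#' Convenience constructor; each edge is given as
#' `list(x, y, mark_at_x, mark_at_y)`.  A directed edge `x -> y` is
#' `list(x, y, "tail", "arrowhead")`, a bidirected edge
#' `list(x, y, "arrowhead", "arrowhead")`, a fully unknown edge
#' `list(x, y, "circle", "circle")`.
#'
#' @param labels Node labels.
#' @param edges List of 4-element edge specifications.
#' @return A `marked_graph`.
#' @export
graph_from_edges <- function(labels, edges = list()) {
  g <- marked_graph(labels)
  for (e in edges) g <- add_edge(g, e[[1]], e[[2]], e[[3]], e[[4]])
  g
}

#' Directed-graph constructor
#'
#' Builds a DAG-style marked graph from `parent -> child` pairs (tails at
#' parents, arrowheads at children).
#'
#' @param labels Node labels.
#' @param arcs List of `c(parent, child)` pairs.
#' @return A `marked_graph` with only directed edges.
#' @export
dag_from_arcs <- function(labels, arcs = list()) {
  g <- marked_graph(labels)
  for (a in arcs) g <- add_edge(g, a[[1]], a[[2]], "tail", "arrowhead")
  g
}

n_nodes <- function(g) length(g$labels)

#' @export
print.marked_graph <- function(x, ...) {
  cat(sprintf("Marked graph with %d nodes and %d edges\n",
              n_nodes(x), nrow(edge_table(x))))
  et <- edge_table(x)
  if (nrow(et)) {
    cat(paste0("  ", format_edge(et), collapse = "\n"), "\n")
  }
  invisible(x)
}

## one row per unordered adjacent pair: x, y, mark at x, mark at y
edge_table <- function(g) {
  a <- g$amat
  idx <- which(a != MARK_ABSENT & upper.tri(a), arr.ind = TRUE)
  data.frame(x = g$labels[idx[, 1]], y = g$labels[idx[, 2]],
             mark_x = a[cbind(idx[, 2], idx[, 1])],
             mark_y = a[idx],
             stringsAsFactors = FALSE)
}

format_edge <- function(et) {
  left  <- c("?", "o", "<", "-")[et$mark_x + 1L]
  right <- c("?", "o", ">", "-")[et$mark_y + 1L]
  paste0(et$x, " ", left, "-", right, " ", et$y)
}

adjacent_nodes <- function(g, i) which(g$amat[i, ] != MARK_ABSENT)

is_adjacent <- function(g, i, j) g$amat[i, j] != MARK_ABSENT

## mark at j on edge i - j (indices)
mark_at <- function(g, i, j) g$amat[i, j]

#' Parents, children, ancestors and descendants via definite directed edges
#'
#' Relations are taken over fully directed edges only (tail at one end,
#' arrowhead at the other); circle marks never contribute.
#'
#' @param g A `marked_graph`.
#' @param x Node label.
#' @return Character vector of node labels (including `x` itself for
#'   `ancestors`/`descendants`).
#' @export
descendants <- function(g, x) {
  i <- node_index(g, x)
  g$labels[reach_directed(g, i, forward = TRUE)]
}

#' @rdname descendants
#' @export
ancestors <- function(g, x) {
  i <- node_index(g, x)
  g$labels[reach_directed(g, i, forward = FALSE)]
}

## directed reachability over edges u -> v (tail at u, arrowhead at v)
reach_directed <- function(g, i, forward = TRUE) {
  a <- g$amat
  p <- n_nodes(g)
  ## child[u, v] TRUE iff u -> v
  child <- (a == MARK_ARROW) & (t(a) == MARK_TAIL)
  if (!forward) child <- t(child)
  seen <- rep(FALSE, p); seen[i] <- TRUE
  frontier <- i
  while (length(frontier)) {
    nxt <- which(colSums(child[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Check ancestral-graph validity
#'
#' An ancestral graph has no directed cycle and no almost-directed cycle
#' (a bidirected edge `x <-> y` together with a directed path `x -> ... -> y`)
#' among its definite (non-circle) edges.  Selection-bias (tail-tail)
#' edges are not modelled and are reported as violations.
#'
#' @param g A `marked_graph`.
#' @return `TRUE`, or `FALSE` with attribute `violations`, a list of
#'   offending node sequences / edge descriptions.
#' @export
is_valid_ancestral <- function(g) {
  a <- g$amat
  p <- n_nodes(g)
  viol <- list()
  child <- (a == MARK_ARROW) & (t(a) == MARK_TAIL)   # child[u,v]: u -> v
  ## directed cycles: strict reachability u -> ... -> u
  reach <- directed_closure(child)
  cyc <- which(diag(reach))
  if (length(cyc)) {
    for (v in cyc) viol[[length(viol) + 1L]] <-
      c("directed cycle through", g$labels[v])
  }
  ## almost-directed cycles: x <-> y with directed path x -> ... -> y
  bidir <- (a == MARK_ARROW) & (t(a) == MARK_ARROW)
  idx <- which(bidir & upper.tri(bidir), arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      x <- idx[r, 1]; y <- idx[r, 2]
      if (reach[x, y] || reach[y, x])
        viol[[length(viol) + 1L]] <-
          c("almost-directed cycle:", g$labels[x], "<->", g$labels[y])
    }
  }
  ## selection-bias edges are outside this package's graph class
  undir <- (a == MARK_TAIL) & (t(a) == MARK_TAIL)
  idx <- which(undir & upper.tri(undir), arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) viol[[length(viol) + 1L]] <-
      c("undirected (selection) edge:", g$labels[idx[r, 1]], "-", g$labels[idx[r, 2]])
  }
  ok <- length(viol) == 0L
  if (!ok) attr(ok, "violations") <- viol
  ok
}

## transitive closure of a boolean relation (strict: no reflexive seed)
directed_closure <- function(rel) {
  p <- nrow(rel)
  reach <- rel
  repeat {
    new <- reach | (reach %*% rel > 0)
    if (identical(new, reach)) break
    reach <- new
  }
  reach
}

#' m-separation in an ancestral graph
#'
#' Decides whether every path between `x` and `y` is blocked given `Z` under
#' ancestral-graph semantics: a non-collider on a path blocks when it is in
#' `Z`; a collider blocks unless it or one of its descendants is in `Z`.
#' Implemented as a breadth-first search over walk states (an edge plus the
#' direction of travel), which is equivalent to path separation and runs in
#' time quadratic in the number of edges.
#'
#' @param g A `marked_graph` with MAG marks (arrowheads/tails).
#' @param x,y Distinct node labels not in `Z`.
#' @param Z Character vector of conditioning node labels (possibly empty).
#' @return Logical scalar: `TRUE` if `x` and `y` are m-separated given `Z`.
#' @export
m_separated <- function(g, x, y, Z = character()) {
  i <- node_index(g, x); j <- node_index(g, y)
  Zi <- if (length(Z)) node_index(g, Z) else integer()
  if (i == j) stop("x and y must differ")
  if (i %in% Zi || j %in% Zi) stop("x and y must not be in Z")
  !m_connected_idx(g, i, j, Zi)
}

m_connected_idx <- function(g, i, j, Zi) {
  a <- g$amat
  p <- n_nodes(g)
  inZ <- rep(FALSE, p); inZ[Zi] <- TRUE
  ## colliders are open iff the node is an ancestor of Z (or in Z)
  anZ <- rep(FALSE, p)
  if (length(Zi)) {
    for (z in Zi) anZ[reach_directed(g, z, forward = FALSE)] <- TRUE
  }
  if (is_adjacent(g, i, j)) return(TRUE)
  ## states: ordered pairs (u, v) meaning the walk traverses edge u - v
  visited <- matrix(FALSE, p, p)
  queue_u <- integer(); queue_v <- integer()
  for (w in adjacent_nodes(g, i)) {
    if (w == j) return(TRUE)
    queue_u <- c(queue_u, i); queue_v <- c(queue_v, w)
    visited[i, w] <- TRUE
  }
  head <- 1L
  while (head <= length(queue_u)) {
    u <- queue_u[head]; v <- queue_v[head]; head <- head + 1L
    for (w in adjacent_nodes(g, v)) {
      if (w == u) next
      collider <- (mark_at(g, u, v) == MARK_ARROW) &&
                  (mark_at(g, w, v) == MARK_ARROW)
      pass <- if (collider) anZ[v] else !inZ[v]
      if (!pass) next
      if (w == j) return(TRUE)
      if (!visited[v, w]) {
        visited[v, w] <- TRUE
        queue_u <- c(queue_u, v); queue_v <- c(queue_v, w)
      }
    }
  }
  FALSE
}

#' Latent projection of a DAG onto its observed nodes
#'
#' Marginalizes the latent nodes of a DAG, returning the maximal ancestral
#' graph over the observed nodes: two observed nodes are adjacent iff they
#' cannot be d-separated by any subset of the remaining observed nodes, and
#' an endpoint carries an arrowhead iff it is not an ancestor (in the DAG)
#' of the other endpoint, a tail otherwise.
#'
#' @param dag A `marked_graph` whose edges are all directed and acyclic.
#' @param latent Character vector of latent node labels.
#' @return A `marked_graph` over the observed nodes with MAG marks.
#' @export
latent_project <- function(dag, latent = character()) {
  if (!isTRUE(is_valid_ancestral(dag))) stop("input must be acyclic")
  et <- edge_table(dag)
  if (nrow(et) && !all((et$mark_x == MARK_TAIL & et$mark_y == MARK_ARROW) |
                       (et$mark_x == MARK_ARROW & et$mark_y == MARK_TAIL)))
    stop("input must contain only directed edges")
  latent <- as.character(latent)
  node_index(dag, latent)  # validate labels
  obs <- setdiff(dag$labels, latent)
  mag <- marked_graph(obs)
  anc <- lapply(obs, function(v) ancestors(dag, v))
  names(anc) <- obs
  no <- length(obs)
  if (no < 2) return(mag)
  for (ii in 1:(no - 1)) for (jj in (ii + 1):no) {
    x <- obs[ii]; y <- obs[jj]
    others <- setdiff(obs, c(x, y))
    sepfound <- FALSE
    for (k in 0:length(others)) {
      if (sepfound) break
      for (S in subsets_of_size(others, k)) {
        if (m_separated(dag, x, y, S)) { sepfound <- TRUE; break }
      }
    }
    if (!sepfound) {
      ## tail at an endpoint iff it is an ancestor of the other endpoint
      mx <- if (x %in% anc[[y]]) MARK_TAIL else MARK_ARROW
      my <- if (y %in% anc[[x]]) MARK_TAIL else MARK_ARROW
      mag <- add_edge(mag, x, y, mx, my)
    }
  }
  mag
}

subsets_of_size <- function(v, k) {
  if (k == 0) return(list(character()))
  if (k > length(v)) return(list())
  cmb <- utils::combn(v, k, simplify = FALSE)
  cmb
}

#' Structural Hamming distance over a node subset
#'
#' Counts, over unordered pairs within `subset`: 1 if the pair's adjacency
#' differs between the two graphs, and, where both graphs have the edge,
#' 1 per endpoint whose mark differs (0 to 2 per edge).
#'
#' @param g1,g2 `marked_graph`s over identical node label sets.
#' @param subset Node labels to restrict to (default: all nodes).
#' @return Non-negative integer.
#' @export
shd <- function(g1, g2, subset = NULL) {
  if (is.null(subset)) {
    if (!setequal(g1$labels, g2$labels))
      stop("graphs must share the same node labels")
    subset <- g1$labels
  }
  if (!all(subset %in% g1$labels) || !all(subset %in% g2$labels))
    stop("subset contains labels absent from one of the graphs")
  idx1 <- node_index(g1, subset)
  idx2 <- node_index(g2, subset)
  a1 <- g1$amat[idx1, idx1, drop = FALSE]
  a2 <- g2$amat[idx2, idx2, drop = FALSE]
  d <- 0L
  p <- length(subset)
  if (p < 2) return(0L)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    adj1 <- a1[i, j] != MARK_ABSENT
    adj2 <- a2[i, j] != MARK_ABSENT
    if (adj1 != adj2) d <- d + 1L
    else if (adj1) {
      if (a1[i, j] != a2[i, j]) d <- d + 1L
      if (a1[j, i] != a2[j, i]) d <- d + 1L
    }
  }
  d
}

#' Possible descendants of a node in a PAG
#'
#' A node `w` is a possible descendant of `x` if there is a path from `x`
#' to `w` on which no edge carries an arrowhead pointing back towards `x`,
#' i.e. every edge leaving a node has a non-arrowhead mark at that node
#' (a possibly-directed path).  `x` is always included.
#'
#' @param p A `marked_graph` with PAG marks.
#' @param x Node label.
#' @return Character vector of node labels.
#' @export
possible_descendants <- function(p, x) {
  i <- node_index(p, x)
  a <- p$amat
  np <- n_nodes(p)
  ## pd[u, v]: the step u -> v is possibly directed (no arrowhead at u)
  pd <- (a != MARK_ABSENT) & (t(a) != MARK_ARROW)
  seen <- rep(FALSE, np); seen[i] <- TRUE
  frontier <- i
  while (length(frontier)) {
    nxt <- which(colSums(pd[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  p$labels[seen]
}

#' Definite status and openness of a PAG path
#'
#' A path has definite status when every interior node is either a definite
#' collider (arrowheads at the node on both path edges) or a definite
#' non-collider (a tail at the node on at least one path edge, or circle
#' marks with the node's path neighbours non-adjacent).  For definite-status
#' paths, openness given `Z` follows d-separation semantics with colliders
#' open when a possible descendant lies in `Z`.
#'
#' @param p A `marked_graph`.
#' @param path Character vector of consecutive node labels.
#' @param Z Conditioning node labels.
#' @return List with `definite_status` and `open` logical flags (`open` is
#'   `NA` when the path does not have definite status).
#' @export
definite_status_open <- function(p, path, Z = character()) {
  idx <- node_index(p, path)
  if (length(idx) < 2) stop("a path needs at least two nodes")
  for (s in 1:(length(idx) - 1))
    if (!is_adjacent(p, idx[s], idx[s + 1]))
      stop(sprintf("'%s' and '%s' are not adjacent: not a path",
                   path[s], path[s + 1]))
  if (anyDuplicated(idx)) stop("not a path: repeated node")
  Zi <- if (length(Z)) node_index(p, Z) else integer()
  open <- TRUE
  for (s in seq_along(idx)[-c(1, length(idx))]) {
    u <- idx[s - 1]; v <- idx[s]; w <- idx[s + 1]
    m1 <- mark_at(p, u, v); m2 <- mark_at(p, w, v)
    if (m1 == MARK_ARROW && m2 == MARK_ARROW) {
      ## definite collider
      pdes <- node_index(p, possible_descendants(p, p$labels[v]))
      if (!any(pdes %in% Zi)) open <- FALSE
    } else if (m1 == MARK_TAIL || m2 == MARK_TAIL ||
               !is_adjacent(p, u, w)) {
      ## definite non-collider
      if (v %in% Zi) open <- FALSE
    } else {
      return(list(definite_status = FALSE, open = NA))
    }
  }
  list(definite_status = TRUE, open = open)
}

#' Enumerate simple paths between two nodes
#'
#' @param g A `marked_graph`.
#' @param x,y Distinct node labels.
#' @param max_len Maximum number of edges per path.
#' @return List of character vectors (node label sequences).
#' @export
all_paths <- function(g, x, y, max_len = Inf) {
  i <- node_index(g, x); j <- node_index(g, y)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) { out[[length(out) + 1L]] <<- g$labels[path]; return() }
    if (length(path) - 1 >= max_len) return()
    for (w in adjacent_nodes(g, v)) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(i)
  out
}
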