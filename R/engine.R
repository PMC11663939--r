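## Constraint-based discovery core, test-agnostic: order-independent stable
## skeleton with a conditioning-set size cap and a pluggable forbidden-test
## filter, RFCI-style unshielded-triple retention with minimal-sepset
## shrinking, conservative majority-rule triple classification, and the
## complete orientation rule set R1-R10 (R5-R7, which only matter under
## selection bias, are gated off by default).

## ---- sepset store ----------------------------------------------------------

new_sepset_store <- function() new.env(parent = emptyenv())

pair_key <- function(i, j) paste(sort(c(i, j)), collapse = "\r")

sepset_set <- function(store, i, j, S, p) {
  assign(pair_key(i, j), list(S = sort(S), p = p), envir = store)
}

sepset_get <- function(store, i, j) {
  get0(pair_key(i, j), envir = store)
}

#' @keywords internal
sepset_dump <- function(store) {
  keys <- ls(store)
  out <- lapply(keys, function(k) {
    v <- get(k, envir = store)
    pr <- strsplit(k, "\r", fixed = TRUE)[[1]]
    list(x = pr[1], y = pr[2], sepset = v$S, p = v$p)
  })
  out
}

## ---- skeleton --------------------------------------------------------------

#' Order-independent ("stable") skeleton search
#'
#' Level-wise edge removal: at each conditioning-set size, the adjacency
#' sets are frozen so that the result does not depend on the order in which
#' variables are processed.  Candidate conditioning sets are subsets of the
#' frozen adjacency set of either endpoint (minus the other endpoint); a
#' pair is disconnected as soon as a test exceeds `alpha`, and the
#' separating set and its p-value are recorded.
#'
#' @param tester A [ci_test()] tester.
#' @param nodes Character vector of variable names to include.
#' @param alpha Significance level (tests with `p > alpha` declare
#'   independence).
#' @param max_cond Maximum conditioning-set size (fixed covariates inside
#'   the tester never count towards it).
#' @param filter Optional `function(i, j, S)` returning `TRUE` for
#'   forbidden test combinations, which are skipped.
#' @return List with `graph` (all-circle `marked_graph`) and `sepsets`
#'   (environment store; see [discovery_details()]).
#' @export
stable_skeleton <- function(tester, nodes, alpha = 0.05, max_cond = Inf,
                            filter = NULL) {
  g <- marked_graph(nodes)
  p <- length(nodes)
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j)
    g$amat[i, j] <- g$amat[j, i] <- MARK_CIRCLE
  store <- new_sepset_store()
  l <- 0L
  repeat {
    adj_frozen <- lapply(seq_len(p), function(i) nodes[adjacent_nodes(g, i)])
    any_candidate <- FALSE
    for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
      x <- nodes[i]; y <- nodes[j]
      if (!is_adjacent(g, i, j)) next
      cands <- level_candidates(adj_frozen[[i]], adj_frozen[[j]], x, y, l)
      if (length(cands)) any_candidate <- TRUE
      for (S in cands) {
        if (!is.null(filter) && isTRUE(filter(x, y, S))) next
        res <- tester$test(x, y, S)
        if (res$p_merged > alpha) {
          g$amat[i, j] <- g$amat[j, i] <- MARK_ABSENT
          sepset_set(store, x, y, S, res$p_merged)
          break
        }
      }
    }
    l <- l + 1L
    if (l > max_cond || !any_candidate) break
  }
  list(graph = g, sepsets = store)
}

## all size-l subsets of adj(x)\{y} plus adj(y)\{x}, deduplicated,
## in deterministic order
level_candidates <- function(adj_x, adj_y, x, y, l) {
  a1 <- sort(setdiff(adj_x, y))
  a2 <- sort(setdiff(adj_y, x))
  cands <- c(subsets_of_size(a1, l),
             if (!identical(a1, a2)) subsets_of_size(a2, l))
  if (l == 0) return(cands[1])
  keys <- vapply(cands, paste, "", collapse = "\r")
  cands[!duplicated(keys)]
}

## ---- RFCI unshielded-triple retention --------------------------------------

unshielded_triples <- function(g) {
  nodes <- g$labels
  p <- length(nodes)
  out <- list()
  for (k in seq_len(p)) {
    nb <- adjacent_nodes(g, k)
    if (length(nb) < 2) next
    for (u in seq_along(nb)) for (v in seq_along(nb)) if (u < v) {
      i <- nb[u]; j <- nb[v]
      if (!is_adjacent(g, i, j)) {
        ends <- sort(c(nodes[i], nodes[j]))  # canonical: alphabetical ends
        out[[length(out) + 1L]] <- c(ends[1], nodes[k], ends[2])
      }
    }
  }
  out
}

#' RFCI-style retention tests on unshielded triples
#'
#' For every unshielded triple `<i, k, j>`, both non-adjacent-pair edges
#' `i - k` and `k - j` are re-tested given the stored separating set of
#' `(i, j)`.  Any independence found removes the edge; a minimal separating
#' set is then recovered by iteratively dropping elements that are not
#' needed for the independence to hold.  The sweep repeats until no further
#' edge is removed.
#'
#' @inheritParams stable_skeleton
#' @param graph Skeleton `marked_graph`.
#' @param sepsets Sepset store from [stable_skeleton()].
#' @return List with updated `graph` and `sepsets`, plus `removed`, the
#'   edges dropped during retention.
#' @export
rfci_triple_retention <- function(graph, sepsets, tester, alpha = 0.05,
                                  filter = NULL) {
  removed <- list()
  repeat {
    changed <- FALSE
    for (tr in unshielded_triples(graph)) {
      i <- tr[1]; k <- tr[2]; j <- tr[3]
      ss <- sepset_get(sepsets, i, j)
      if (is.null(ss)) next
      for (pair in list(c(i, k), c(j, k))) {
        a <- pair[1]; b <- pair[2]
        ia <- node_index(graph, a); ib <- node_index(graph, b)
        if (!is_adjacent(graph, ia, ib)) next
        S <- setdiff(ss$S, c(a, b))
        if (!is.null(filter) && isTRUE(filter(a, b, S))) next
        res <- tester$test(a, b, S)
        if (res$p_merged > alpha) {
          graph$amat[ia, ib] <- graph$amat[ib, ia] <- MARK_ABSENT
          minS <- shrink_sepset(tester, a, b, S, alpha, filter)
          sepset_set(sepsets, a, b, minS$S, minS$p)
          removed[[length(removed) + 1L]] <- c(a, b)
          changed <- TRUE
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  list(graph = graph, sepsets = sepsets, removed = removed)
}

## iteratively drop elements whose removal preserves independence
shrink_sepset <- function(tester, a, b, S, alpha, filter = NULL) {
  p_cur <- tester$test(a, b, S)$p_merged
  repeat {
    dropped <- FALSE
    for (z in S) {
      S2 <- setdiff(S, z)
      if (!is.null(filter) && isTRUE(filter(a, b, S2))) next
      res <- tester$test(a, b, S2)
      if (res$p_merged > alpha) {
        S <- S2; p_cur <- res$p_merged; dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  list(S = S, p = p_cur)
}

## ---- majority-rule triple classification -----------------------------------

#' Conservative majority-rule classification of unshielded triples
#'
#' For each unshielded triple `<i, k, j>`, all subsets (up to `max_cond`)
#' of the adjacency sets of `i` and of `j` that render `i` and `j`
#' independent are collected; `q` is the fraction of those separating sets
#' containing `k`.  The triple is a collider when `q < 1/2`, a non-collider
#' when `q > 1/2`, and ambiguous at a tie.  When no separating subset is
#' found the stored skeleton sepset decides membership.
#'
#' @inheritParams rfci_triple_retention
#' @param max_cond Maximum size of the voted conditioning sets.
#' @return Data frame with columns `i`, `k`, `j`, `status`
#'   (`"collider"`, `"noncollider"`, `"ambiguous"`), `q` and `n_sepsets`.
#' @export
classify_triples <- function(graph, sepsets, tester, alpha = 0.05,
                             max_cond = Inf, filter = NULL) {
  trs <- unshielded_triples(graph)
  rows <- lapply(trs, function(tr) {
    i <- tr[1]; k <- tr[2]; j <- tr[3]
    seps <- voting_sepsets(graph, tester, i, j, alpha, max_cond, filter)
    if (length(seps) == 0) {
      ss <- sepset_get(sepsets, i, j)
      q <- if (!is.null(ss) && k %in% ss$S) 1 else 0
      nsep <- 0L
    } else {
      q <- mean(vapply(seps, function(S) k %in% S, TRUE))
      nsep <- length(seps)
    }
    status <- if (q < 0.5) "collider" else if (q > 0.5) "noncollider" else "ambiguous"
    data.frame(i = i, k = k, j = j, status = status, q = q,
               n_sepsets = nsep, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(i = character(), k = character(), j = character(),
                      status = character(), q = numeric(),
                      n_sepsets = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

voting_sepsets <- function(graph, tester, i, j, alpha, max_cond,
                           filter = NULL) {
  ii <- node_index(graph, i); jj <- node_index(graph, j)
  a1 <- sort(setdiff(graph$labels[adjacent_nodes(graph, ii)], j))
  a2 <- sort(setdiff(graph$labels[adjacent_nodes(graph, jj)], i))
  seen <- character()
  out <- list()
  for (side in list(a1, a2)) {
    kmax <- min(length(side), max_cond)
    for (l in 0:kmax) for (S in subsets_of_size(side, l)) {
      key <- paste(S, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      if (!is.null(filter) && isTRUE(filter(i, j, S))) next
      if (tester$test(i, j, S)$p_merged > alpha)
        out[[length(out) + 1L]] <- S
    }
  }
  out
}

triple_status <- function(triples, i, k, j) {
  if (!nrow(triples)) return(NA_character_)
  a <- min(i, j); b <- max(i, j)
  hit <- triples$i == a & triples$k == k & triples$j == b
  if (!any(hit)) return(NA_character_)
  triples$status[which(hit)[1]]
}

## ---- orientation -----------------------------------------------------------

#' Orient v-structures from classified triples
#'
#' Every triple classified as a collider receives arrowheads at its middle
#' node on both edges; ambiguous triples are left untouched.
#'
#' @param graph All-circle skeleton `marked_graph`.
#' @param triples Output of [classify_triples()].
#' @return The partially oriented `marked_graph`.
#' @export
orient_v_structures <- function(graph, triples) {
  if (nrow(triples)) for (r in seq_len(nrow(triples))) {
    if (triples$status[r] != "collider") next
    i <- node_index(graph, triples$i[r])
    k <- node_index(graph, triples$k[r])
    j <- node_index(graph, triples$j[r])
    graph$amat[i, k] <- MARK_ARROW
    graph$amat[j, k] <- MARK_ARROW
  }
  graph
}

## mutable orientation state: environment with amat, conflicts, log
orient_state <- function(graph) {
  st <- new.env(parent = emptyenv())
  st$g <- graph
  st$conflicts <- list()
  st$log <- list()
  st$changed <- FALSE
  st
}

## set mark at j on edge i - j; invariant marks are never overridden
## (first write wins, later contradictions are logged as conflicts)
set_mark <- function(st, i, j, mark, rule) {
  cur <- st$g$amat[i, j]
  if (cur == MARK_ABSENT) return(invisible(FALSE))
  if (cur == mark) return(invisible(FALSE))
  if (cur != MARK_CIRCLE) {
    st$conflicts[[length(st$conflicts) + 1L]] <-
      list(rule = rule, edge = c(st$g$labels[i], st$g$labels[j]),
           existing = cur, attempted = mark)
    return(invisible(FALSE))
  }
  st$g$amat[i, j] <- mark
  st$changed <- TRUE
  st$log[[length(st$log) + 1L]] <-
    list(rule = rule, edge = c(st$g$labels[i], st$g$labels[j]), mark = mark)
  invisible(TRUE)
}

#' Apply the complete orientation rules to a partially oriented graph
#'
#' Runs rules R1-R4 and R8-R10 to a fixed point (R5-R7 only concern
#' selection bias and are skipped unless `selection_rules = TRUE`; enabling
#' them is unsupported in this release).  Orientations driven by an
#' unshielded triple (R1, R3) never fire on a triple classified ambiguous.
#' R4 (discriminating paths) consults the stored separating sets.
#' Contradictory demands on an already-invariant mark are logged as
#' conflicts and do not override the earlier mark.
#'
#' @param graph `marked_graph` with v-structures (and any background
#'   arrowheads) already oriented.
#' @param triples Classification from [classify_triples()].
#' @param sepsets Sepset store.
#' @param selection_rules Must be `FALSE`; placeholder for R5-R7.
#' @param validate Error when the oriented graph is not a valid ancestral
#'   graph (directed or almost-directed cycle among definite edges)?  With
#'   `FALSE` the violations are attached as an attribute instead, matching
#'   the behaviour of unchecked RFCI output on unfaithful data.
#' @return The oriented graph, with attributes `conflicts`, `rule_log` and
#'   (when `validate = FALSE`) `violations`.
#' @export
apply_orientation_rules <- function(graph, triples, sepsets,
                                    selection_rules = FALSE,
                                    validate = TRUE) {
  if (selection_rules)
    stop("selection-bias rules R5-R7 are not supported (no selection-bias edges)")
  st <- orient_state(graph)
  repeat {
    st$changed <- FALSE
    rule_R1(st, triples)
    rule_R2(st)
    rule_R3(st, triples)
    rule_R4(st, sepsets)
    rule_R8(st)
    rule_R9(st)
    rule_R10(st)
    if (!st$changed) break
  }
  ok <- is_valid_ancestral(st$g)
  if (!isTRUE(ok)) {
    msg <- paste(vapply(attr(ok, "violations"), paste, "", collapse = " "),
                 collapse = "; ")
    if (validate)
      stop("orientation produced an invalid ancestral graph: ", msg,
           "; rule trace: ",
           paste(vapply(st$log, function(l)
             paste0(l$rule, ":", l$edge[1], "-", l$edge[2]), ""),
             collapse = " "))
  }
  out <- st$g
  attr(out, "conflicts") <- st$conflicts
  attr(out, "rule_log") <- st$log
  if (!isTRUE(ok)) attr(out, "violations") <- attr(ok, "violations")
  out
}

## R1: a *-> b o-* c, a and c non-adjacent, <a,b,c> unambiguous -> b -> c
rule_R1 <- function(st, triples) {
  g <- st$g; p <- n_nodes(g); lab <- g$labels
  for (b in seq_len(p)) {
    arrows_in <- which(g$amat[, b] == MARK_ARROW)
    circ_at_b <- which(g$amat[, b] == MARK_CIRCLE & t(g$amat)[, b] != MARK_ABSENT)
    for (a in arrows_in) for (cc in circ_at_b) {
      if (a == cc || is_adjacent(g, a, cc)) next
      status <- triple_status(triples, lab[a], lab[b], lab[cc])
      if (identical(status, "ambiguous")) next
      if (set_mark(st, b, cc, MARK_ARROW, "R1") |
          set_mark(st, cc, b, MARK_TAIL, "R1")) g <- st$g
    }
  }
}

## R2: a -> b *-> c or a *-> b -> c, with a *-o c  =>  a *-> c
rule_R2 <- function(st) {
  g <- st$g; p <- n_nodes(g)
  for (a in seq_len(p)) for (cc in seq_len(p)) {
    if (a == cc || g$amat[a, cc] != MARK_CIRCLE) next
    for (b in seq_len(p)) {
      if (b == a || b == cc) next
      dir_ab <- g$amat[a, b] == MARK_ARROW && g$amat[b, a] == MARK_TAIL
      into_c <- g$amat[b, cc] == MARK_ARROW
      into_b <- g$amat[a, b] == MARK_ARROW
      dir_bc <- g$amat[b, cc] == MARK_ARROW && g$amat[cc, b] == MARK_TAIL
      if ((dir_ab && into_c) || (into_b && dir_bc)) {
        if (set_mark(st, a, cc, MARK_ARROW, "R2")) g <- st$g
        break
      }
    }
  }
}

## R3: a *-> b <-* c, a *-o t o-* c, a, c non-adjacent, t *-o b => t *-> b
rule_R3 <- function(st, triples) {
  g <- st$g; p <- n_nodes(g); lab <- g$labels
  for (b in seq_len(p)) for (t in seq_len(p)) {
    if (b == t || g$amat[t, b] != MARK_CIRCLE) next
    arrows_b <- which(g$amat[, b] == MARK_ARROW)
    circ_t <- which(g$amat[, t] == MARK_CIRCLE)
    cand <- intersect(arrows_b, circ_t)
    cand <- setdiff(cand, c(b, t))
    if (length(cand) < 2) next
    for (u in seq_along(cand)) for (v in seq_along(cand)) if (u < v) {
      a <- cand[u]; cc <- cand[v]
      if (is_adjacent(g, a, cc)) next
      status <- triple_status(triples, lab[a], lab[t], lab[cc])
      if (identical(status, "ambiguous")) next
      if (set_mark(st, t, b, MARK_ARROW, "R3")) g <- st$g
    }
  }
}

## R4: discriminating path <theta, ..., a, b, c> for b with b o-* c:
## if b in sepset(theta, c) orient b -> c, else a <-> b <-> c
rule_R4 <- function(st, sepsets) {
  g <- st$g; p <- n_nodes(g); lab <- g$labels
  for (b in seq_len(p)) for (cc in seq_len(p)) {
    if (b == cc || g$amat[cc, b] != MARK_CIRCLE) next
    dp <- find_discriminating_path(st$g, b, cc)
    if (is.null(dp)) next
    theta <- dp[1]
    a <- dp[length(dp) - 1L]
    ss <- sepset_get(sepsets, lab[theta], lab[cc])
    if (!is.null(ss) && lab[b] %in% ss$S) {
      set_mark(st, cc, b, MARK_TAIL, "R4")   # tail at b
      set_mark(st, b, cc, MARK_ARROW, "R4")  # arrowhead at c
    } else {
      set_mark(st, b, a, MARK_ARROW, "R4")
      set_mark(st, a, b, MARK_ARROW, "R4")
      set_mark(st, cc, b, MARK_ARROW, "R4")
      set_mark(st, b, cc, MARK_ARROW, "R4")
    }
    g <- st$g
  }
}

## search a discriminating path <theta, d1, ..., dk, b> for b w.r.t. c:
## every d is a collider on the path and a parent of c; theta, c non-adjacent
find_discriminating_path <- function(g, b, cc) {
  parents_c <- which(g$amat[, cc] == MARK_ARROW & t(g$amat)[, cc] == MARK_TAIL)
  found <- NULL
  dfs <- function(path) {
    if (!is.null(found)) return()
    cur <- path[length(path)]
    for (w in adjacent_nodes(g, cur)) {
      if (!is.null(found)) return()
      if (w %in% path || w == cc) next
      ## arrowhead at cur from the w side completes cur's collider
      ## requirement (cur == b has no such requirement)
      if (cur != b && g$amat[w, cur] != MARK_ARROW) next
      if (cur == b && g$amat[b, w] != MARK_ARROW) {
        ## first step: dk needs an arrowhead at dk on the b - dk edge
        next
      }
      if (!is_adjacent(g, w, cc)) {
        if (length(path) >= 2) { found <<- c(w, rev(path)); return() }
        next
      }
      ## w must be an interior collider candidate: a parent of c with an
      ## arrowhead at w from cur's side
      if (!(w %in% parents_c)) next
      if (g$amat[cur, w] != MARK_ARROW) next
      dfs(c(path, w))
    }
  }
  dfs(b)
  found
}

## R8: a o-> c and (a -> b -> c or a -o b -> c)  =>  a -> c
rule_R8 <- function(st) {
  g <- st$g; p <- n_nodes(g)
  for (a in seq_len(p)) for (cc in seq_len(p)) {
    if (a == cc) next
    if (!(g$amat[a, cc] == MARK_ARROW && g$amat[cc, a] == MARK_CIRCLE)) next
    for (b in seq_len(p)) {
      if (b == a || b == cc) next
      dir_bc <- g$amat[b, cc] == MARK_ARROW && g$amat[cc, b] == MARK_TAIL
      if (!dir_bc) next
      dir_ab <- g$amat[a, b] == MARK_ARROW && g$amat[b, a] == MARK_TAIL
      tcirc_ab <- g$amat[a, b] == MARK_CIRCLE && g$amat[b, a] == MARK_TAIL
      if (dir_ab || tcirc_ab) { set_mark(st, cc, a, MARK_TAIL, "R8"); break }
    }
  }
}

## uncovered possibly-directed paths from a to c (as index vectors)
upd_paths <- function(g, a, cc) {
  out <- list()
  dfs <- function(path) {
    cur <- path[length(path)]
    if (cur == cc) { out[[length(out) + 1L]] <- path; return() }
    for (w in adjacent_nodes(g, cur)) {
      if (w %in% path) next
      ## possibly directed: no arrowhead at cur on the cur - w edge
      if (g$amat[w, cur] == MARK_ARROW) next
      ## uncovered: predecessor of cur must not be adjacent to w
      if (length(path) >= 2 && is_adjacent(g, path[length(path) - 1L], w)) next
      dfs(c(path, w))
    }
  }
  dfs(a)
  out
}

## R9: a o-> c, uncovered p.d. path <a, b, ..., c> with b, c non-adjacent
rule_R9 <- function(st) {
  g <- st$g; p <- n_nodes(g)
  for (a in seq_len(p)) for (cc in seq_len(p)) {
    if (a == cc) next
    if (!(g$amat[a, cc] == MARK_ARROW && g$amat[cc, a] == MARK_CIRCLE)) next
    paths <- upd_paths(g, a, cc)
    hit <- any(vapply(paths, function(pp) {
      length(pp) >= 3 && !is_adjacent(g, pp[2], cc)
    }, TRUE))
    if (hit) set_mark(st, cc, a, MARK_TAIL, "R9")
  }
}

## R10: a o-> c, b -> c <- t, uncovered p.d. paths p1: a..b, p2: a..t whose
## first steps m, w differ and are non-adjacent  =>  a -> c
rule_R10 <- function(st) {
  g <- st$g; p <- n_nodes(g)
  for (a in seq_len(p)) for (cc in seq_len(p)) {
    if (a == cc) next
    if (!(g$amat[a, cc] == MARK_ARROW && g$amat[cc, a] == MARK_CIRCLE)) next
    par_c <- which(g$amat[, cc] == MARK_ARROW & t(g$amat)[, cc] == MARK_TAIL)
    par_c <- setdiff(par_c, a)
    if (length(par_c) < 2) next
    done <- FALSE
    for (b in par_c) for (t in par_c) {
      if (done || b >= t) next
      p1 <- upd_paths(g, a, b)
      p2 <- upd_paths(g, a, t)
      for (x in p1) for (y in p2) {
        m <- if (length(x) >= 2) x[2] else NULL
        w <- if (length(y) >= 2) y[2] else NULL
        if (is.null(m) || is.null(w)) next
        if (m != w && !is_adjacent(g, m, w)) {
          set_mark(st, cc, a, MARK_TAIL, "R10")
          done <- TRUE
          break
        }
      }
    }
  }
}
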