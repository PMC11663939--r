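## The anchorFCI algorithm: conservative RFCI extended with reliable-anchor
## selection and integration of the partial order "anchors precede the
## variables of interest" (anchors are known not to be caused by any
## interest variable, e.g. SNP genotypes relative to phenotypes).

#' Variable roles for anchored discovery
#'
#' Partitions the columns of a dataset into the variables of interest, the
#' anchor candidates (known non-descendants of every interest variable),
#' and fixed covariates conditioned on in every test.
#'
#' @param interest Character vector of interest variable names.
#' @param anchors Character vector of anchor-candidate names.
#' @param covariates Character vector of fixed-covariate names.
#' @return An object of class `variable_roles`.
#' @export
variable_roles <- function(interest, anchors = character(),
                           covariates = character()) {
  interest <- as.character(interest)
  anchors <- as.character(anchors)
  covariates <- as.character(covariates)
  if (!length(interest)) stop("at least one interest variable is required")
  overlap <- c(intersect(interest, anchors), intersect(interest, covariates),
               intersect(anchors, covariates))
  if (length(overlap))
    stop("roles must be disjoint; shared: ", paste(unique(overlap), collapse = ", "))
  structure(list(interest = interest, anchors = anchors,
                 covariates = covariates), class = "variable_roles")
}

#' @export
print.variable_roles <- function(x, ...) {
  cat("Variable roles\n")
  cat("  interest:  ", paste(x$interest, collapse = ", "), "\n")
  cat("  anchors:   ", paste(x$anchors, collapse = ", "), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Forbidden-test filter implied by the partial order
#'
#' Independence tests between two anchor variables conditioned on any
#' interest variable are skipped during the adapted skeleton search: a
#' minimal separating set for two anchors can never contain a
#' non-ancestor, so the restriction loses nothing and avoids the least
#' reliable tests.
#'
#' @param roles A [variable_roles()] object.
#' @return `function(i, j, S)` returning `TRUE` when the test is forbidden.
#' @export
anchor_skeleton_filter <- function(roles) {
  anchors <- roles$anchors
  interest <- roles$interest
  function(i, j, S) {
    (i %in% anchors) && (j %in% anchors) && any(S %in% interest)
  }
}

#' Screen anchor candidates for association with the interest set
#'
#' Each candidate is tested, marginally but adjusted for the fixed
#' covariates, against every interest variable with a single-predictor
#' nested likelihood-ratio test (the interest variable is the outcome).
#' A candidate passes when any of its p-values is at most `alpha_screen`.
#'
#' @param tester A `ci_tester` over the data (for an oracle tester the
#'   merged oracle p-value is used instead of an LRT).
#' @param roles A [variable_roles()] object.
#' @param alpha_screen Screening threshold, default `1e-5` (genome-wide
#'   suggestive association).
#' @return Data frame with columns `candidate`, `min_p`, `best_interest`,
#'   `screened`.
#' @export
screen_anchor_candidates <- function(tester, roles, alpha_screen = 1e-5) {
  cands <- roles$anchors
  if (!length(cands))
    return(data.frame(candidate = character(), min_p = numeric(),
                      best_interest = character(), screened = logical(),
                      stringsAsFactors = FALSE))
  rows <- lapply(cands, function(a) {
    ps <- vapply(roles$interest, function(y) {
      if (identical(tester$kind, "oracle")) {
        tester$test(a, y, character())$p_merged
      } else {
        tester$env$lrt(y, character(), a)$p
      }
    }, 0.0)
    data.frame(candidate = a, min_p = min(ps),
               best_interest = roles$interest[which.min(ps)],
               screened = min(ps) <= alpha_screen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select reliable anchors from a first-pass discovery run
#'
#' A screened candidate is a reliable anchor when it is adjacent to at
#' least one interest variable in the first-pass skeleton and every
#' unshielded triple containing it was classified unambiguous by the
#' majority rule (strict reading: one ambiguous triple disqualifies).
#'
#' @param graph First-pass skeleton (`marked_graph`).
#' @param triples First-pass [classify_triples()] table.
#' @param roles A [variable_roles()] object.
#' @param candidates Candidates that survived screening.
#' @return Character vector of selected anchors.
#' @export
select_reliable_anchors <- function(graph, triples, roles,
                                    candidates = roles$anchors) {
  keep <- vapply(candidates, function(a) {
    ia <- node_index(graph, a)
    adj <- graph$labels[adjacent_nodes(graph, ia)]
    if (!any(adj %in% roles$interest)) return(FALSE)
    if (nrow(triples)) {
      mine <- triples$i == a | triples$k == a | triples$j == a
      if (any(triples$status[mine] == "ambiguous")) return(FALSE)
    }
    TRUE
  }, TRUE)
  candidates[keep]
}

#' Enforce non-ancestral arrowheads on anchor--interest edges
#'
#' Every edge between an anchor and an interest variable receives an
#' arrowhead at the interest endpoint (anchors cannot be caused by
#' interest variables).  An existing tail there means the data contradict
#' the declared partial order and is an error.
#'
#' @param graph Partially oriented `marked_graph`.
#' @param anchors Selected anchor labels present in `graph`.
#' @param roles A [variable_roles()] object.
#' @return The graph with enforced arrowheads.
#' @export
enforce_anchor_arrowheads <- function(graph, anchors, roles) {
  for (a in anchors) {
    ia <- node_index(graph, a)
    for (iv in adjacent_nodes(graph, ia)) {
      v <- graph$labels[iv]
      if (!v %in% roles$interest) next
      cur <- graph$amat[ia, iv]  # mark at the interest endpoint
      if (cur == MARK_TAIL)
        stop(sprintf(paste0("non-ancestral knowledge violated: edge %s - %s ",
                            "carries a tail at the interest endpoint"), a, v))
      graph$amat[ia, iv] <- MARK_ARROW
    }
  }
  graph
}

## shared engine pipeline: skeleton -> retention -> triples -> R0 ->
## (optional enforcement) -> R1-R10
run_engine <- function(tester, nodes, alpha = 0.05, max_cond = Inf,
                       filter = NULL, enforce = NULL, validate = TRUE) {
  sk <- stable_skeleton(tester, nodes, alpha, max_cond, filter)
  rt <- rfci_triple_retention(sk$graph, sk$sepsets, tester, alpha, filter)
  tt <- classify_triples(rt$graph, rt$sepsets, tester, alpha, max_cond, filter)
  g0 <- orient_v_structures(rt$graph, tt)
  if (!is.null(enforce)) g0 <- enforce(g0)
  pag <- apply_orientation_rules(g0, tt, rt$sepsets, validate = validate)
  list(pag = pag, skeleton = rt$graph, sepsets = rt$sepsets, triples = tt,
       removed = rt$removed, violations = attr(pag, "violations"),
       conflicts = attr(pag, "conflicts"), rule_log = attr(pag, "rule_log"))
}

resolve_tester <- function(data, types, fixed_covariates, tester) {
  if (!is.null(tester)) return(tester)
  if (is.null(data)) stop("provide either data (with types) or a tester")
  mixed_ci_tester(data, types, fixed_covariates)
}

#' Conservative RFCI with the majority rule
#'
#' Fits a partial ancestral graph by the conservative RFCI procedure:
#' order-independent stable skeleton, RFCI unshielded-triple retention,
#' majority-rule triple classification, v-structure orientation and the
#' complete orientation rules.  No background knowledge is used; this is
#' the baseline that [anchorfci()] extends.
#'
#' @param data Data frame of complete observations (omit when `tester` is
#'   supplied).
#' @param types Named vector of column types (`continuous`, `binary`,
#'   `multinomial`).
#' @param fixed_covariates Columns appended to every conditioning set.
#' @param nodes Variables to include (default: all non-covariate columns).
#' @param alpha Significance level for the independence tests.
#' @param max_cond Conditioning-set size cap (`Inf` for none; the fixed
#'   covariates never count).
#' @param tester Optional pre-built `ci_tester` (e.g. an oracle).
#' @return An object of class `rfci_fit` with elements `pag`, `triples`,
#'   `sepsets`, `conflicts`, `rule_log`, `n_tests`, `config`.
#' @export
rfci <- function(data = NULL, types = NULL, fixed_covariates = character(),
                 nodes = NULL, alpha = 0.05, max_cond = Inf, tester = NULL) {
  tester <- resolve_tester(data, types, fixed_covariates, tester)
  if (is.null(nodes)) nodes <- tester$labels
  ## unchecked output, like classic RFCI: unfaithful data may yield an
  ## invalid ancestral graph, which is reported, not an error
  eng <- run_engine(tester, nodes, alpha, max_cond, validate = FALSE)
  structure(list(pag = strip_attrs(eng$pag), skeleton = eng$skeleton,
                 triples = eng$triples, sepsets = sepset_dump(eng$sepsets),
                 violations = eng$violations,
                 conflicts = eng$conflicts, rule_log = eng$rule_log,
                 n_tests = ci_test_count(tester),
                 config = list(alpha = alpha, max_cond = max_cond),
                 call = match.call()),
            class = "rfci_fit")
}

strip_attrs <- function(g) {
  attr(g, "conflicts") <- NULL
  attr(g, "rule_log") <- NULL
  attr(g, "violations") <- NULL
  g
}

#' Causal discovery with reliable anchors (anchorFCI)
#'
#' Fits a partial ancestral graph over the interest variables and a set of
#' reliable anchors.  The pipeline: (1) screen anchor candidates for
#' association with the interest set; (2) first-pass conservative RFCI run
#' over interest plus screened candidates; (3) keep as reliable anchors the
#' candidates adjacent to the interest set whose every unshielded triple is
#' unambiguous; (4) second-pass run on interest plus selected anchors with
#' the adapted skeleton search (no anchor--anchor test conditions on an
#' interest variable) and with arrowheads enforced at the interest end of
#' every anchor--interest edge before the orientation rules; (5) validity
#' check of the result as an ancestral graph.
#'
#' @inheritParams rfci
#' @param roles A [variable_roles()] object.
#' @param screen_alpha Screening threshold for candidate--interest
#'   association (default `1e-5`); use `1` to admit all candidates.
#' @return An object of class `anchorfci_fit` with elements `pag`,
#'   `anchors` (selected), `anchor_report`, `triples`, `sepsets`,
#'   `conflicts`, `rule_log`, `n_tests`, `config`.
#' @examples
#' sys <- toy_anchor_system()
#' fit <- anchorfci(tester = oracle_ci_tester(sys$mag), roles = sys$roles)
#' fit
#' @export
anchorfci <- function(data = NULL, roles, types = NULL,
                      fixed_covariates = roles$covariates,
                      alpha = 0.05, max_cond = Inf, screen_alpha = 1e-5,
                      tester = NULL) {
  stopifnot(inherits(roles, "variable_roles"))
  tester <- resolve_tester(data, types, fixed_covariates, tester)
  missing_vars <- setdiff(c(roles$interest, roles$anchors), tester$labels)
  if (length(missing_vars))
    stop("variables not in the data: ", paste(missing_vars, collapse = ", "))

  screen <- screen_anchor_candidates(tester, roles, screen_alpha)
  screened <- screen$candidate[screen$screened]

  selected <- character()
  phase1 <- NULL
  if (length(screened)) {
    ## selection pass: only the skeleton and triple table are consumed, so
    ## ancestral validity of its oriented graph is not enforced here
    phase1 <- run_engine(tester, c(roles$interest, screened), alpha, max_cond,
                         validate = FALSE)
    selected <- select_reliable_anchors(phase1$skeleton, phase1$triples,
                                        roles, screened)
  }

  filter <- if (length(selected)) anchor_skeleton_filter(roles) else NULL
  enforce <- if (length(selected))
    function(g) enforce_anchor_arrowheads(g, selected, roles) else NULL
  eng <- run_engine(tester, c(roles$interest, selected), alpha, max_cond,
                    filter = filter, enforce = enforce)

  ## the partial order must never be contradicted in the output
  check_no_interest_to_anchor(eng$pag, selected, roles)

  report <- anchor_report(screen, phase1, roles, selected)
  structure(list(pag = strip_attrs(eng$pag), anchors = selected,
                 anchor_report = report, skeleton = eng$skeleton,
                 triples = eng$triples, sepsets = sepset_dump(eng$sepsets),
                 conflicts = eng$conflicts, rule_log = eng$rule_log,
                 phase1 = if (!is.null(phase1))
                   list(skeleton = phase1$skeleton, triples = phase1$triples),
                 n_tests = ci_test_count(tester),
                 config = list(alpha = alpha, max_cond = max_cond,
                               screen_alpha = screen_alpha),
                 roles = roles, call = match.call()),
            class = "anchorfci_fit")
}

check_no_interest_to_anchor <- function(pag, anchors, roles) {
  for (a in anchors) {
    ia <- node_index(pag, a)
    for (iv in adjacent_nodes(pag, ia)) {
      v <- pag$labels[iv]
      if (!v %in% roles$interest) next
      if (pag$amat[iv, ia] == MARK_ARROW && pag$amat[ia, iv] == MARK_TAIL)
        stop(sprintf("invalid output: definite edge %s -> %s into an anchor",
                     v, a))
    }
  }
  invisible(TRUE)
}

anchor_report <- function(screen, phase1, roles, selected) {
  rep <- screen
  rep$adjacent_interest <- integer(nrow(rep))
  rep$ambiguous_triples <- integer(nrow(rep))
  if (!is.null(phase1)) {
    for (r in seq_len(nrow(rep))) {
      a <- rep$candidate[r]
      if (!rep$screened[r] || !a %in% phase1$skeleton$labels) next
      ia <- node_index(phase1$skeleton, a)
      adj <- phase1$skeleton$labels[adjacent_nodes(phase1$skeleton, ia)]
      rep$adjacent_interest[r] <- sum(adj %in% roles$interest)
      tt <- phase1$triples
      if (nrow(tt)) {
        mine <- tt$i == a | tt$k == a | tt$j == a
        rep$ambiguous_triples[r] <- sum(tt$status[mine] == "ambiguous")
      }
    }
  }
  rep$selected <- rep$candidate %in% selected
  rep
}

#' @export
print.anchorfci_fit <- function(x, ...) {
  cat("anchorFCI fit\n")
  cat(sprintf("  %d interest variables, %d/%d anchor candidates selected\n",
              length(x$roles$interest), length(x$anchors),
              length(x$roles$anchors)))
  cat(sprintf("  alpha = %g, max conditioning size = %s\n",
              x$config$alpha, format(x$config$max_cond)))
  cat("  PAG edges:\n")
  et <- edge_table(x$pag)
  if (nrow(et)) cat(paste0("    ", format_edge(et), collapse = "\n"), "\n")
  if (length(x$conflicts))
    cat(sprintf("  NOTE: %d orientation conflict(s); run is unstable\n",
                length(x$conflicts)))
  invisible(x)
}

#' @export
print.rfci_fit <- function(x, ...) {
  cat("Conservative RFCI fit (majority rule)\n")
  cat(sprintf("  alpha = %g, max conditioning size = %s\n",
              x$config$alpha, format(x$config$max_cond)))
  cat("  PAG edges:\n")
  et <- edge_table(x$pag)
  if (nrow(et)) cat(paste0("    ", format_edge(et), collapse = "\n"), "\n")
  if (length(x$conflicts))
    cat(sprintf("  NOTE: %d orientation conflict(s); run is unstable\n",
                length(x$conflicts)))
  invisible(x)
}

#' @export
summary.anchorfci_fit <- function(object, ...) {
  tt <- object$triples
  out <- list(
    n_edges = nrow(edge_table(object$pag)),
    anchors = object$anchors,
    anchor_report = object$anchor_report,
    triple_counts = if (nrow(tt)) table(tt$status) else table(character()),
    n_tests = object$n_tests,
    n_conflicts = length(object$conflicts)
  )
  class(out) <- "summary.anchorfci_fit"
  out
}

#' @export
print.summary.anchorfci_fit <- function(x, ...) {
  cat("anchorFCI summary\n")
  cat(sprintf("  edges: %d; conflicts: %d\n", x$n_edges, x$n_conflicts))
  cat("  selected anchors:", if (length(x$anchors))
    paste(x$anchors, collapse = ", ") else "(none)", "\n")
  cat("  triples:", paste(names(x$triple_counts), x$triple_counts,
                          sep = "=", collapse = ", "), "\n")
  cat(sprintf("  CI tests: %d queries, %d fitted\n",
              x$n_tests[["queries"]], x$n_tests[["fitted"]]))
  print(x$anchor_report)
  invisible(x)
}

#' Bootstrap edge-type stability
#'
#' Re-runs [anchorfci()] on bootstrap resamples of the rows and tallies,
#' for every variable pair, the relative frequency of each edge type
#' (including absence and, for unselected anchors, absence from the graph).
#'
#' @inheritParams anchorfci
#' @param B Number of bootstrap replicates.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return An object of class `stability_table`: data frame of pair, edge
#'   type and frequency, with attribute `n_ok` (successful replicates).
#' @export
bootstrap_stability <- function(data, roles, types,
                                fixed_covariates = roles$covariates,
                                alpha = 0.05, max_cond = Inf,
                                screen_alpha = 1e-5, B = 50, seed = 1) {
  stopifnot(B >= 1)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  vars <- c(roles$interest, roles$anchors)
  tally <- new.env(parent = emptyenv())
  n_ok <- 0L; failures <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- sample.int(nrow(data), replace = TRUE)
    fit <- tryCatch(
      anchorfci(data[idx, , drop = FALSE], roles, types, fixed_covariates,
                alpha, max_cond, screen_alpha),
      error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    n_ok <- n_ok + 1L
    for (ui in seq_along(vars)) for (vi in seq_along(vars)) if (ui < vi) {
      u <- vars[ui]; v <- vars[vi]
      type <- edge_type_string(fit$pag, u, v)
      key <- paste(u, v, type, sep = "\r")
      assign(key, (get0(key, envir = tally) %||% 0L) + 1L, envir = tally)
    }
  }
  if (failures) warning(failures, " bootstrap replicate(s) failed and were excluded")
  if (n_ok == 0L) stop("all bootstrap replicates failed")
  keys <- ls(tally)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(x = parts[, 1], y = parts[, 2], edge = parts[, 3],
                    freq = vapply(keys, function(k) get(k, envir = tally), 0L) / n_ok,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$x, out$y, -out$freq), ]
  attr(out, "n_ok") <- n_ok
  class(out) <- c("stability_table", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

edge_type_string <- function(pag, u, v) {
  if (!u %in% pag$labels || !v %in% pag$labels) return("not in graph")
  iu <- node_index(pag, u); iv <- node_index(pag, v)
  if (!is_adjacent(pag, iu, iv)) return("absent")
  mu <- pag$amat[iv, iu]; mv <- pag$amat[iu, iv]
  left <- c("?", "o", "<", "-")[mu + 1L]
  right <- c("?", "o", ">", "-")[mv + 1L]
  paste0(left, "-", right)
}
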