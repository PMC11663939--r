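## Independent brute-force oracles used to validate the package's graph
## algorithms.  These enumerate simple paths explicitly and apply the
## separation definitions directly; they share no code with the package's
## reachability-based implementations.

## all simple paths between two node indices, as index vectors
bf_paths <- function(g, i, j) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == j) { out[[length(out) + 1L]] <<- path; return() }
    nb <- which(g$amat[v, ] != 0)
    for (w in nb) if (!w %in% path) walk(c(path, w))
  }
  walk(i)
  out
}

## descendants (via directed edges) of a node index, including itself
bf_descendants <- function(g, i) {
  a <- g$amat
  desc <- i
  repeat {
    kids <- unique(unlist(lapply(desc, function(v)
      which(a[v, ] == 2 & a[, v] == 3))))
    new <- setdiff(kids, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  desc
}

## m-separation by exhaustive path enumeration
bf_m_separated <- function(g, x, y, Z = character()) {
  i <- match(x, g$labels); j <- match(y, g$labels)
  Zi <- match(Z, g$labels)
  for (path in bf_paths(g, i, j)) {
    open <- TRUE
    if (length(path) > 2) for (s in 2:(length(path) - 1)) {
      u <- path[s - 1]; v <- path[s]; w <- path[s + 1]
      collider <- g$amat[u, v] == 2 && g$amat[w, v] == 2
      if (collider) {
        if (!any(bf_descendants(g, v) %in% Zi)) { open <- FALSE; break }
      } else {
        if (v %in% Zi) { open <- FALSE; break }
      }
    }
    if (open) return(FALSE)
  }
  TRUE
}

## possible descendants by enumeration of possibly-directed paths
bf_possible_descendants <- function(g, x) {
  i <- match(x, g$labels)
  p <- length(g$labels)
  hits <- i
  for (j in setdiff(seq_len(p), i)) {
    for (path in bf_paths(g, i, j)) {
      ok <- TRUE
      for (s in 1:(length(path) - 1)) {
        ## arrowhead pointing back towards x's side blocks
        if (g$amat[path[s + 1], path[s]] == 2) { ok <- FALSE; break }
      }
      if (ok) { hits <- c(hits, j); break }
    }
  }
  sort(g$labels[hits])
}

## random MAG generator used by property tests: random DAG + latents,
## projected by the package (projection itself is cross-validated elsewhere)
random_test_mag <- function(n_obs = 6, n_latent = 1, edge_prob = 0.35,
                            seed = 1) {
  set.seed(seed)
  obs <- LETTERS[seq_len(n_obs)]
  lat <- if (n_latent > 0) paste0("L", seq_len(n_latent)) else character()
  nodes <- c(obs, lat)
  ord <- sample(nodes)
  arcs <- list()
  for (u in seq_along(ord)) for (v in seq_along(ord)) {
    if (u < v && runif(1) < edge_prob)
      arcs[[length(arcs) + 1L]] <- c(ord[u], ord[v])
  }
  ## latents act as roots (confounders): drop arcs into latents
  arcs <- Filter(function(a) !a[2] %in% lat, arcs)
  dag <- dag_from_arcs(nodes, arcs)
  list(dag = dag, mag = latent_project(dag, lat), latent = lat, obs = obs)
}

## a ci_tester stub with scripted p-values: `script` maps
## "i|j|S1,S2" (pair sorted, S sorted) to a p-value; default p = 0
scripted_tester <- function(labels, script) {
  env <- new.env(parent = emptyenv())
  env$n_queries <- 0L; env$n_fitted <- 0L
  test <- function(i, j, S = character()) {
    env$n_queries <- env$n_queries + 1L
    env$n_fitted <- env$n_fitted + 1L
    key <- paste0(paste(sort(c(i, j)), collapse = "|"), "|",
                  paste(sort(S), collapse = ","))
    p <- if (!is.null(script[[key]])) script[[key]] else 0
    list(p1 = p, p2 = p, p_merged = p, df = c(NA, NA), flags = c("stub", "stub"))
  }
  structure(list(test = test, labels = labels, types = NULL,
                 fixed_covariates = character(), env = env, kind = "stub"),
            class = "ci_tester")
}

## a tester that records every query passed to an inner tester
recording_tester <- function(inner) {
  env <- inner$env
  log <- new.env(parent = emptyenv())
  log$queries <- list()
  test <- function(i, j, S = character()) {
    log$queries[[length(log$queries) + 1L]] <- list(i = i, j = j, S = sort(S))
    inner$test(i, j, S)
  }
  structure(list(test = test, labels = inner$labels, types = inner$types,
                 fixed_covariates = inner$fixed_covariates, env = env,
                 kind = inner$kind, qlog = log),
            class = "ci_tester")
}

## the worked 8-node example (three anchors), plus the PAG a plain
## conservative run on one unfaithful finite-sample draw was observed to
## produce (edge B -> G3 wrongly directed into an anchor): their distance
## is a fixed regression value for the SHD
worked_mag_system <- function() toy_anchor_system()

worked_unfaithful_rfci_pag <- function() {
  graph_from_edges(
    c("G1", "G2", "G3", "A", "B", "C", "D", "E"),
    list(list("G1", "A", "circle", "circle"),
         list("G2", "D", "circle", "arrowhead"),
         list("B", "G3", "tail", "arrowhead"),
         list("A", "C", "circle", "arrowhead"),
         list("B", "C", "circle", "arrowhead"),
         list("C", "E", "arrowhead", "circle"),
         list("B", "E", "arrowhead", "circle"),
         list("B", "D", "arrowhead", "arrowhead")))
}
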