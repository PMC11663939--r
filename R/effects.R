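## Causal-effect identifiability and estimation from a learned PAG:
## edge visibility (no latent confounding between the endpoints), the
## generalized backdoor criterion, and covariate-adjustment estimation of
## post-interventional expectations/probabilities with bootstrap intervals.

#' Visibility of a directed PAG edge
#'
#' A definite edge `x -> y` is visible when `x` and `y` provably share no
#' latent cause: there is a node `v` not adjacent to `y` with `v *-> x`,
#' or a collider path into `x`, starting at such a `v`, whose interior
#' nodes are all parents of `y`.
#'
#' @param p A `marked_graph` (PAG).
#' @param x,y Node labels; the edge `x -> y` must be definitely directed.
#' @return Logical scalar.
#' @export
is_visible <- function(p, x, y) {
  ix <- node_index(p, x); iy <- node_index(p, y)
  if (!(p$amat[ix, iy] == MARK_ARROW && p$amat[iy, ix] == MARK_TAIL))
    stop(sprintf("edge %s -> %s is not definitely directed", x, y))
  cand_v <- setdiff(which(!apply_adjacency(p, iy)), c(ix, iy))
  for (v in cand_v) {
    ## clause 1: v *-> x directly
    if (p$amat[v, ix] == MARK_ARROW) return(TRUE)
    ## clause 2: collider path v ... -> x, interior nodes parents of y
    if (collider_path_into(p, v, ix, iy)) return(TRUE)
  }
  FALSE
}

apply_adjacency <- function(p, i) p$amat[i, ] != MARK_ABSENT

## exists a path v, d1, ..., dk, x (k >= 1) with every d a collider on the
## path and a parent of y, and the last edge into x
collider_path_into <- function(p, v, ix, iy) {
  parents_y <- which(p$amat[, iy] == MARK_ARROW & t(p$amat)[, iy] == MARK_TAIL)
  found <- FALSE
  dfs <- function(path) {
    if (found) return()
    cur <- path[length(path)]
    for (w in adjacent_nodes(p, cur)) {
      if (found) return()
      if (w %in% path) next
      if (cur == v) {
        ## first edge v *-> d1 needs an arrowhead at d1
        if (p$amat[v, w] != MARK_ARROW) next
      } else {
        ## interior collider: arrowheads at cur from both sides
        if (p$amat[w, cur] != MARK_ARROW) next
        if (p$amat[cur, w] != MARK_ARROW) next
      }
      if (w == ix) {
        if (length(path) >= 2) { found <<- TRUE; return() }
        next
      }
      if (!w %in% parents_y) next
      dfs(c(path, w))
    }
  }
  dfs(v)
  found
}

#' Find a generalized backdoor adjustment set
#'
#' Searches subsets (smallest first, up to `size_cap`) of the nodes that
#' are neither `x`, `y`, nor possible descendants of `x`, for a set `Z`
#' that blocks every definite-status backdoor path from `x` to `y`
#' (paths whose first edge has an arrowhead at `x`).  The empty set is
#' returned immediately when no backdoor path exists.
#'
#' @param p A `marked_graph` (PAG).
#' @param x,y Node labels.
#' @param size_cap Maximum size of the candidate sets (default 4).
#' @return Character vector `Z` (possibly empty), or `NULL` when no
#'   admissible set exists within the cap.
#' @export
find_backdoor_set <- function(p, x, y, size_cap = 4) {
  if (x == y) stop("x and y must differ")
  ix <- node_index(p, x)
  bdp <- backdoor_paths(p, x, y)
  if (!length(bdp)) return(character())
  cands <- setdiff(p$labels, c(x, y, possible_descendants(p, x)))
  for (k in 0:min(size_cap, length(cands))) {
    for (Z in subsets_of_size(sort(cands), k)) {
      if (blocks_all(p, bdp, Z)) return(Z)
    }
  }
  NULL
}

backdoor_paths <- function(p, x, y) {
  ix <- node_index(p, x)
  paths <- all_paths(p, x, y)
  Filter(function(pp) {
    w <- node_index(p, pp[2])
    p$amat[w, ix] == MARK_ARROW  # first edge into x
  }, paths)
}

blocks_all <- function(p, paths, Z) {
  for (pp in paths) {
    st <- definite_status_open(p, pp, Z)
    if (st$definite_status && isTRUE(st$open)) return(FALSE)
  }
  TRUE
}

#' Estimate an interventional expectation or probability by adjustment
#'
#' Fits a regression of `y` on `x`, the adjustment set `Z` and the fixed
#' covariates (Gaussian for continuous `y`, logistic for binary), then for
#' each treatment value in `grid` averages the fitted response over the
#' observed `(z_i, covariate_i)`: the empirical version of the backdoor
#' adjustment formula.  With `Z` and covariates empty this reduces to the
#' plain regression prediction `E(Y | X = x)`.  Confidence intervals are
#' nonparametric bootstrap percentiles.
#'
#' @param data Complete data frame.
#' @param x,y Treatment and outcome column names.
#' @param Z Character vector of adjustment columns (possibly empty).
#' @param grid Treatment values to evaluate; defaults to the observed
#'   levels (binary/multinomial x) or deciles (continuous x).
#' @param types Named column types.
#' @param fixed_covariates Columns always included in the regression.
#' @param transform Scale for continuous outcomes: `"none"`, `"log"`, or
#'   `"rint"`; estimates are reported on the modelling scale (naive mean
#'   back-transformation for `"log"` when `smearing = TRUE`).
#' @param smearing Apply naive smearing back-transformation for
#'   log-modelled outcomes.
#' @param B Bootstrap replicates for the confidence interval.
#' @param level Confidence level.
#' @param seed Seed for the bootstrap.
#' @return Data frame of class `do_estimate`: one row per grid value with
#'   `x_value`, `estimate`, `lower`, `upper`, `n_boot`.
#' @export
estimate_do <- function(data, x, y, Z = character(), grid = NULL,
                        types, fixed_covariates = character(),
                        transform = c("none", "log", "rint"),
                        smearing = FALSE, B = 500, level = 0.95, seed = 1) {
  transform <- match.arg(transform)
  if (anyNA(data[, c(x, y, Z, fixed_covariates)]))
    stop("missing values in the modelling columns")
  types <- check_types(data, types)
  if (is.null(grid)) grid <- default_grid(data[[x]], types[[x]])
  rng <- range(as.numeric(data[[x]]))
  if (types[[x]] == "continuous" &&
      any(grid < rng[1] | grid > rng[2]))
    warning("extrapolation: grid value(s) outside the observed support of ", x)

  fit_fun <- make_do_fitter(x, y, Z, types, fixed_covariates, transform,
                            smearing)
  point <- fit_fun(data, grid)
  set.seed(seed)
  boot <- replicate(B, {
    idx <- sample.int(nrow(data), replace = TRUE)
    tryCatch(fit_fun(data[idx, , drop = FALSE], grid),
             error = function(e) rep(NA_real_, length(grid)))
  })
  boot <- matrix(boot, nrow = length(grid))
  alpha2 <- (1 - level) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(alpha2, 1 - alpha2),
              na.rm = TRUE)
  out <- data.frame(x_value = grid, estimate = point,
                    lower = ci[1, ], upper = ci[2, ],
                    n_boot = colSums(!is.na(t(boot))))
  class(out) <- c("do_estimate", class(out))
  attr(out, "treatment") <- x
  attr(out, "outcome") <- y
  attr(out, "Z") <- Z
  out
}

default_grid <- function(xv, xtype) {
  if (xtype == "continuous")
    unname(stats::quantile(as.numeric(xv), probs = seq(0.1, 0.9, by = 0.1)))
  else sort(unique(as.numeric(xv)))
}

make_do_fitter <- function(x, y, Z, types, fixed_covariates, transform,
                           smearing) {
  rhs_vars <- c(x, Z, fixed_covariates)
  function(d, grid) {
    dd <- d
    ## discrete predictors as factors so indicator coding applies
    for (v in rhs_vars) if (types[[v]] != "continuous")
      dd[[v]] <- factor(dd[[v]])
    yv <- dd[[y]]
    if (types[[y]] == "continuous") {
      yv <- switch(transform, none = as.numeric(yv),
                   log = log(as.numeric(yv)),
                   rint = rank_inverse_normal(as.numeric(yv)))
      dd[[y]] <- yv
      fml <- stats::reformulate(rhs_vars, response = y)
      fit <- stats::lm(fml, data = dd)
      sm <- if (smearing && transform == "log")
        mean(exp(stats::residuals(fit))) else 1
      vapply(grid, function(g) {
        nd <- dd; nd[[x]] <- coerce_like(g, dd[[x]])
        pr <- stats::predict(fit, newdata = nd)
        if (smearing && transform == "log") mean(exp(pr) * sm) else mean(pr)
      }, 0.0)
    } else if (types[[y]] == "binary") {
      dd[[y]] <- as.numeric(factor(dd[[y]])) - 1
      fml <- stats::reformulate(rhs_vars, response = y)
      fit <- stats::glm(fml, data = dd, family = stats::binomial())
      vapply(grid, function(g) {
        nd <- dd; nd[[x]] <- coerce_like(g, dd[[x]])
        mean(stats::predict(fit, newdata = nd, type = "response"))
      }, 0.0)
    } else {
      stop("multinomial outcomes are not supported for effect estimation")
    }
  }
}

coerce_like <- function(g, template) {
  if (is.factor(template)) factor(rep(as.character(g), length(template)),
                                  levels = levels(template))
  else rep(as.numeric(g), length(template))
}

#' Effect report for every identifiable directed edge
#'
#' For each definite directed edge among the interest variables, checks
#' visibility, searches a generalized backdoor set, re-validates it, and
#' estimates the do-response over a default grid.  Edges that are not
#' visible or have no admissible set are reported with the reason.
#'
#' @param p A `marked_graph` (PAG) or an `anchorfci_fit`/`rfci_fit`.
#' @param data Complete data frame.
#' @param roles A [variable_roles()] object.
#' @param types Named column types.
#' @param size_cap Backdoor search cap.
#' @param B Bootstrap replicates per estimate.
#' @param seed Seed.
#' @return List with `estimates` (list of [estimate_do()] outputs, named
#'   `x->y`) and `skipped` (data frame of edge and reason).
#' @export
effects_report <- function(p, data, roles, types, size_cap = 4, B = 200,
                           seed = 1) {
  if (inherits(p, c("rfci_fit", "anchorfci_fit"))) p <- p$pag
  types <- check_types(data, types)
  et <- edge_table(p)
  estimates <- list()
  skipped <- list()
  skip <- function(x, y, why)
    skipped[[length(skipped) + 1L]] <<- data.frame(x = x, y = y, reason = why)
  if (nrow(et)) for (r in seq_len(nrow(et))) {
    x <- et$x[r]; y <- et$y[r]
    ## orient the pair as the definite edge if there is one
    if (et$mark_x[r] == MARK_ARROW && et$mark_y[r] == MARK_TAIL) {
      tmp <- x; x <- y; y <- tmp
    } else if (!(et$mark_x[r] == MARK_TAIL && et$mark_y[r] == MARK_ARROW)) {
      next  # not definitely directed
    }
    if (!(x %in% roles$interest && y %in% roles$interest)) next
    if (!is_visible(p, x, y)) { skip(x, y, "possibly confounded (not visible)"); next }
    Z <- find_backdoor_set(p, x, y, size_cap)
    if (is.null(Z)) { skip(x, y, "no admissible backdoor set found"); next }
    ## independent re-validation of the adjustment set
    if (!backdoor_admissible(p, x, y, Z)) {
      skip(x, y, "candidate set failed re-validation"); next
    }
    if (types[[y]] == "multinomial") { skip(x, y, "multinomial outcome"); next }
    est <- estimate_do(data, x, y, Z, grid = NULL, types = types,
                       fixed_covariates = roles$covariates, B = B, seed = seed)
    estimates[[paste0(x, "->", y)]] <- est
  }
  list(estimates = estimates,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(x = character(), y = character(),
                                 reason = character()))
}

#' Re-validate a backdoor adjustment set
#'
#' Checks, independently of how `Z` was produced, that `Z` contains no
#' possible descendant of `x` and blocks every definite-status backdoor
#' path from `x` to `y`.
#'
#' @inheritParams find_backdoor_set
#' @param Z Candidate adjustment set.
#' @return Logical scalar.
#' @export
backdoor_admissible <- function(p, x, y, Z) {
  if (any(Z %in% possible_descendants(p, x))) return(FALSE)
  if (any(Z %in% c(x, y))) return(FALSE)
  blocks_all(p, backdoor_paths(p, x, y), Z)
}
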