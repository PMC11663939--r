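## Conditional-independence testing for mixed data.
##
## The symmetric test of a pair (Vi, Vj) given a set S fits, for each of the
## two variables in turn, a reduced regression on S and a full regression on
## S plus the other variable, compares them with a nested likelihood-ratio
## test, and merges the two p-values as min(2 * min(p1, p2), max(p1, p2)).
## Families: Gaussian linear (continuous outcomes, rank-INT transformed),
## logistic (binary), multinomial log-linear (multinomial).  A fixed
## covariate set is appended to every conditioning set.

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their offset ranks,
#' `qnorm((rank - c) / (n - 2c + 1))`, with average ranks for ties and the
#' Blom offset `c = 3/8` by default.  Monotone in its input.
#'
#' @param values Numeric vector with at least two finite values.
#' @param offset Rank offset `c` (default `3/8`).
#' @return Numeric vector of transformed values.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (sum(is.finite(values)) < 2) stop("need at least two finite values")
  if (length(unique(values[is.finite(values)])) < 2)
    stop("rank transform undefined for a constant vector")
  r <- rank(values, ties.method = "average", na.last = "keep")
  n <- sum(!is.na(values))
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

## ---- column encodings ------------------------------------------------------

VAR_TYPES <- c("continuous", "binary", "multinomial")

check_types <- function(data, types) {
  types <- unlist(types)
  miss <- setdiff(names(data), names(types))
  if (length(miss))
    stop("no type declared for column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unname(types[names(data)]), VAR_TYPES)
  if (length(bad)) stop("unknown variable type: ", paste(bad, collapse = ", "))
  types[names(data)]
}

## predictor encoding: a numeric matrix (indicator contrasts for discrete
## levels beyond the first)
encode_predictor <- function(x, type) {
  if (type == "continuous") return(matrix(as.numeric(x), ncol = 1))
  f <- factor(x)
  lev <- levels(f)
  if (length(lev) < 2) stop("discrete predictor with a single level")
  if (type == "binary" && length(lev) != 2)
    stop("binary variable with ", length(lev), " levels")
  m <- sapply(lev[-1], function(l) as.numeric(f == l))
  matrix(m, ncol = length(lev) - 1)
}

## ---- likelihood-ratio engines ---------------------------------------------

## Gaussian LRT with unknown variance: 2 (l_f - l_r) = n log(RSS_r / RSS_f)
lrt_gaussian <- function(y, Xr, Xf) {
  fr <- stats::lm.fit(Xr, y)
  ff <- stats::lm.fit(Xf, y)
  rss_r <- sum(fr$residuals^2)
  rss_f <- sum(ff$residuals^2)
  df <- ff$rank - fr$rank
  if (df <= 0) return(list(p = 1, df = 0L, flag = "none"))
  if (rss_f <= .Machine$double.eps * length(y))
    return(list(p = 0, df = df, flag = "degenerate"))
  stat <- length(y) * log(rss_r / rss_f)
  list(p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
       df = df, flag = "none")
}

lrt_binomial <- function(y, Xr, Xf) {
  flag <- "none"
  fit1 <- fit2 <- NULL
  withCallingHandlers({
    fit1 <- stats::glm.fit(Xr, y, family = stats::binomial())
    fit2 <- stats::glm.fit(Xf, y, family = stats::binomial())
  }, warning = function(w) {
    if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
      flag <<- "separation"
    invokeRestart("muffleWarning")
  })
  if (is.null(fit1) || is.null(fit2) || !fit1$converged || !fit2$converged)
    return(list(p = 0, df = NA_integer_, flag = "nonconvergence"))
  df <- fit2$rank - fit1$rank
  if (df <= 0) return(list(p = 1, df = 0L, flag = flag))
  if (flag == "separation")
    return(list(p = 0, df = df, flag = flag))
  stat <- fit1$deviance - fit2$deviance
  list(p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
       df = df, flag = flag)
}

lrt_multinomial <- function(y, Xr, Xf) {
  ## y: factor with >= 2 levels; matrices include an intercept column,
  ## which multinom adds itself, so strip it
  fit_one <- function(X) {
    if (ncol(X) > 1) {
      d <- data.frame(.y = y, X[, -1, drop = FALSE])
      nnet::multinom(.y ~ ., data = d, trace = FALSE, maxit = 200)
    } else {
      nnet::multinom(y ~ 1, trace = FALSE, maxit = 200)
    }
  }
  res <- tryCatch({
    f1 <- fit_one(Xr); f2 <- fit_one(Xf)
    list(f1 = f1, f2 = f2)
  }, error = function(e) NULL)
  if (is.null(res))
    return(list(p = 0, df = NA_integer_, flag = "nonconvergence"))
  df <- res$f2$edf - res$f1$edf
  if (df <= 0) return(list(p = 1, df = 0L, flag = "none"))
  stat <- res$f1$deviance - res$f2$deviance
  list(p = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
       df = df, flag = "none")
}

run_lrt <- function(ydat, ytype, Xr, Xf) {
  switch(ytype,
         continuous  = lrt_gaussian(ydat, Xr, Xf),
         binary      = lrt_binomial(ydat, Xr, Xf),
         multinomial = lrt_multinomial(ydat, Xr, Xf))
}

#' Nested likelihood-ratio test for one outcome
#'
#' Compares the regression of `outcome` on `reduced` against the regression
#' on `full` (a superset), with the family chosen by the outcome's type:
#' Gaussian linear for continuous outcomes (rank-INT transformed), logistic
#' for binary, multinomial log-linear for multinomial.  Discrete predictors
#' enter as level-indicator contrasts.  Non-convergence or separation is
#' treated as evidence of dependence (p-value 0) and flagged.
#'
#' @param data Complete data frame.
#' @param outcome Outcome column name.
#' @param reduced,full Character vectors of predictor column names,
#'   `reduced` a strict subset of `full`.
#' @param types Named vector of column types (`continuous`, `binary`,
#'   `multinomial`).
#' @param fixed_covariates Columns appended to both predictor sets.
#' @return List with elements `p`, `df` and `flag`.
#' @export
nested_lrt <- function(data, outcome, reduced, full, types,
                       fixed_covariates = character()) {
  tester <- mixed_ci_tester(data, types, fixed_covariates)
  env <- environment(tester$test)
  env$lrt(outcome, union(reduced, character()), setdiff(full, reduced))
}

#' Symmetric mixed-data conditional-independence tester
#'
#' Returns a tester object whose `test(i, j, S)` function evaluates the two
#' null hypotheses `P(Vi | S) = P(Vi | Vj, S)` and `P(Vj | S) = P(Vj | Vi, S)`
#' with nested likelihood-ratio tests and merges the p-values as
#' `min(2 * min(p1, p2), max(p1, p2))`.  The fixed covariates are appended
#' to every conditioning set (and never count towards conditioning-set size
#' caps).  Continuous variables are rank-INT transformed once, up front, for
#' use as Gaussian outcomes; raw values serve as predictors.  Results are
#' cached, so the test is exactly symmetric in (i, j).
#'
#' @param data Complete data frame (no missing values).
#' @param types Named vector of column types.
#' @param fixed_covariates Column names conditioned on in every test.
#' @return An object of class `ci_tester` with elements `test` (function),
#'   `labels`, and bookkeeping accessors; see [ci_test()].
#' @export
mixed_ci_tester <- function(data, types, fixed_covariates = character()) {
  if (!is.data.frame(data)) data <- as.data.frame(data)
  if (anyNA(data)) {
    nmiss <- colSums(is.na(data))
    stop("missing values in column(s): ",
         paste(sprintf("%s (%d)", names(nmiss)[nmiss > 0], nmiss[nmiss > 0]),
               collapse = ", "),
         "; impute before testing")
  }
  types <- check_types(data, types)
  labels <- setdiff(names(data), fixed_covariates)
  for (v in labels) {
    if (length(unique(data[[v]])) < 2)
      stop("constant column: ", v)
  }
  n <- nrow(data)
  ## outcome representations
  ydat <- lapply(names(data), function(v) {
    switch(types[[v]],
           continuous  = rank_inverse_normal(as.numeric(data[[v]])),
           binary      = as.numeric(factor(data[[v]])) - 1,
           multinomial = factor(data[[v]]))
  })
  names(ydat) <- names(data)
  ## predictor encodings
  xenc <- lapply(names(data), function(v) encode_predictor(data[[v]], types[[v]]))
  names(xenc) <- names(data)
  intercept <- matrix(1, n, 1)
  cov_block <- if (length(fixed_covariates))
    do.call(cbind, xenc[fixed_covariates]) else NULL
  base_X <- if (is.null(cov_block)) intercept else cbind(intercept, cov_block)

  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$n_queries <- 0L
  env$n_fitted <- 0L
  env$log <- list()

  design <- function(vars) {
    if (!length(vars)) return(base_X)
    cbind(base_X, do.call(cbind, xenc[vars]))
  }
  lrt <- function(outcome, given, added) {
    Xr <- design(given)
    Xf <- design(c(given, added))
    run_lrt(ydat[[outcome]], types[[outcome]], Xr, Xf)
  }
  env$lrt <- lrt

  test <- function(i, j, S = character()) {
    if (i == j || i %in% S || j %in% S)
      stop("i and j must be distinct and not in S")
    key <- paste(c(sort(c(i, j)), "|", sort(S)), collapse = "\r")
    env$n_queries <- env$n_queries + 1L
    hit <- get0(key, envir = env$cache)
    if (!is.null(hit)) return(hit)
    env$n_fitted <- env$n_fitted + 1L
    o <- c(i, j)[order(c(i, j))]
    r1 <- lrt(o[1], S, o[2])
    r2 <- lrt(o[2], S, o[1])
    res <- list(p1 = r1$p, p2 = r2$p,
                p_merged = merge_pvalues(r1$p, r2$p),
                df = c(r1$df, r2$df),
                flags = c(r1$flag, r2$flag))
    assign(key, res, envir = env$cache)
    res
  }

  structure(list(test = test, labels = labels, types = types,
                 fixed_covariates = fixed_covariates, env = env,
                 kind = "mixed"),
            class = "ci_tester")
}

#' Merge two dependent p-values
#'
#' `min(2 * min(p1, p2), max(p1, p2))`: never exceeds the Bonferroni-2 bound
#' and equals `p` at the fixed point `p1 = p2 = p`.
#'
#' @param p1,p2 Probabilities.
#' @return Merged p-value.
#' @export
merge_pvalues <- function(p1, p2) {
  pmin(2 * pmin(p1, p2), pmax(p1, p2))
}

#' Oracle conditional-independence tester from a MAG
#'
#' Returns a tester whose merged p-value is 1 when the queried pair is
#' m-separated in `mag` given the conditioning set, and 0 otherwise.  Used
#' to compute population-level ("true") PAGs in simulations.
#'
#' @param mag A `marked_graph` with MAG marks.
#' @return A `ci_tester`.
#' @export
oracle_ci_tester <- function(mag) {
  env <- new.env(parent = emptyenv())
  env$n_queries <- 0L
  env$n_fitted <- 0L
  test <- function(i, j, S = character()) {
    env$n_queries <- env$n_queries + 1L
    env$n_fitted <- env$n_fitted + 1L
    p <- as.numeric(m_separated(mag, i, j, S))
    list(p1 = p, p2 = p, p_merged = p, df = c(NA_integer_, NA_integer_),
         flags = c("oracle", "oracle"))
  }
  structure(list(test = test, labels = mag$labels, types = NULL,
                 fixed_covariates = character(), env = env, kind = "oracle"),
            class = "ci_tester")
}

#' Run a conditional-independence test
#'
#' @param tester A `ci_tester`.
#' @param i,j Variable names.
#' @param S Conditioning variable names.
#' @return A list with `p1`, `p2`, `p_merged`, `df`, `flags`.
#' @export
ci_test <- function(tester, i, j, S = character()) {
  stopifnot(inherits(tester, "ci_tester"))
  tester$test(i, j, S)
}

#' Number of distinct tests a tester has evaluated
#'
#' @param tester A `ci_tester`.
#' @return Named integer vector with `queries` (all calls) and `fitted`
#'   (cache misses, i.e. tests actually computed).
#' @export
ci_test_count <- function(tester) {
  c(queries = tester$env$n_queries, fitted = tester$env$n_fitted)
}

#' @export
print.ci_tester <- function(x, ...) {
  cat(sprintf("<ci_tester: %s, %d variables", x$kind, length(x$labels)))
  if (length(x$fixed_covariates))
    cat(sprintf(", %d fixed covariates", length(x$fixed_covariates)))
  cat(sprintf(", %d tests evaluated>\n", x$env$n_fitted))
  invisible(x)
}
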