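## Readers and writers: PAG endpoint-mark matrices as CSV (coding
## 0 = absent, 1 = circle, 2 = arrowhead, 3 = tail; entry [i, j] = mark at
## j on edge i - j), DOT export for visualization, roles/type configuration
## as YAML or JSON, and a validating dataset reader.

#' Write / read a PAG endpoint-mark matrix
#'
#' CSV with a header row of node labels; entry `[i, j]` is the integer mark
#' at `j` on the edge `i - j`.  `read_pag(write_pag(g))` is the identity.
#'
#' @param g A `marked_graph`.
#' @param path File path.
#' @return `write_pag` returns `path` invisibly; `read_pag` returns a
#'   `marked_graph`.
#' @export
write_pag <- function(g, path) {
  m <- g$amat
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pag
#' @export
read_pag <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("mark matrix must be square")
  bad <- which(matrix(!(m %in% 0:3), nrow(m)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid mark code at row %d, column %d",
                 bad[1, 1], bad[1, 2]))
  asym <- which((m == 0) != (t(m) == 0), arr.ind = TRUE)
  if (length(asym))
    stop(sprintf("asymmetric adjacency between '%s' and '%s'",
                 colnames(m)[asym[1, 1]], colnames(m)[asym[1, 2]]))
  marked_graph(colnames(m), m)
}

#' Export a marked graph to DOT
#'
#' Edge ends are decorated by mark: arrowheads as `normal`, circles as
#' `odot`, tails as `none`.
#'
#' @param g A `marked_graph`.
#' @param path Optional file path; when `NULL` the DOT source is returned.
#' @return The DOT source, invisibly when written to file.
#' @export
write_dot <- function(g, path = NULL) {
  dec <- function(m) c("none", "odot", "normal", "none")[m + 1L]
  et <- edge_table(g)
  lines <- c("graph pag {", "  edge [dir=both];",
             sprintf("  \"%s\";", g$labels))
  if (nrow(et)) lines <- c(lines, vapply(seq_len(nrow(et)), function(r) {
    sprintf("  \"%s\" -- \"%s\" [arrowtail=%s, arrowhead=%s];",
            et$x[r], et$y[r], dec(et$mark_x[r]), dec(et$mark_y[r]))
  }, ""))
  lines <- c(lines, "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(path)) return(src)
  writeLines(src, path)
  invisible(src)
}

#' Read a roles/types configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON file with fields `interest`, `anchors`,
#' `covariates` (each a list of column names) and `types` (a map from
#' column name to `continuous`/`binary`/`multinomial`).
#'
#' @param path Configuration file path.
#' @return List with `roles` (a [variable_roles()]) and `types` (named
#'   character vector).
#' @export
read_roles <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  roles <- variable_roles(unlist(cfg$interest),
                          unlist(cfg$anchors %||% character()),
                          unlist(cfg$covariates %||% character()))
  types <- unlist(cfg$types)
  if (is.null(types)) stop("configuration must declare column types")
  list(roles = roles, types = types)
}

#' Read and validate a dataset against a roles configuration
#'
#' The CSV must contain every column named by the roles; binary columns
#' must take exactly two values coded 0/1, multinomial columns integer
#' codes; missing values are an error (impute upstream).
#'
#' @param path CSV file with header.
#' @param roles_path Roles/types configuration (see [read_roles()]).
#' @return List with `data`, `types`, `roles`.
#' @export
read_dataset <- function(path, roles_path) {
  cfg <- read_roles(roles_path)
  data <- utils::read.csv(path, check.names = FALSE)
  need <- c(cfg$roles$interest, cfg$roles$anchors, cfg$roles$covariates)
  absent <- setdiff(need, names(data))
  if (length(absent))
    stop("column(s) missing from the data: ", paste(absent, collapse = ", "))
  data <- data[, need, drop = FALSE]
  nmiss <- colSums(is.na(data))
  if (any(nmiss > 0))
    stop(sum(nmiss), " missing values in column(s): ",
         paste(names(nmiss)[nmiss > 0], collapse = ", "))
  types <- check_types(data, cfg$types)
  for (v in need) {
    if (types[[v]] == "binary" && !all(data[[v]] %in% c(0, 1)))
      stop("binary column not coded 0/1: ", v)
    if (types[[v]] == "multinomial" && !all(data[[v]] == round(data[[v]])))
      stop("multinomial column must be integer-coded: ", v)
  }
  list(data = data, types = types, roles = cfg$roles)
}

#' Plot a marked graph or a fitted PAG
#'
#' Circular layout with mark-decorated edge ends: arrowheads drawn as
#' arrows, circles as open dots, tails plain.
#'
#' @param x A `marked_graph` (or a fit; see methods).
#' @param highlight Optional node labels drawn in a second colour
#'   (e.g. anchors).
#' @param ... Unused.
#' @return Invisibly, the node coordinates.
#' @export
plot.marked_graph <- function(x, highlight = character(), ...) {
  p <- n_nodes(x)
  theta <- seq(0, 2 * pi, length.out = p + 1)[-(p + 1)]
  xy <- cbind(cos(theta), sin(theta))
  oldpar <- graphics::par(mar = c(1, 1, 1, 1)); on.exit(graphics::par(oldpar))
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), axes = FALSE,
                 xlab = "", ylab = "", asp = 1)
  et <- edge_table(x)
  if (nrow(et)) for (r in seq_len(nrow(et))) {
    i <- node_index(x, et$x[r]); j <- node_index(x, et$y[r])
    draw_marked_edge(xy[i, ], xy[j, ], et$mark_x[r], et$mark_y[r])
  }
  cols <- ifelse(x$labels %in% highlight, "tomato", "steelblue")
  graphics::points(xy, pch = 21, bg = cols, cex = 3)
  graphics::text(xy, labels = x$labels, cex = 0.7)
  invisible(xy)
}

draw_marked_edge <- function(p1, p2, m1, m2) {
  shrink <- 0.12
  d <- p2 - p1; len <- sqrt(sum(d^2)); u <- d / len
  a <- p1 + u * shrink; b <- p2 - u * shrink
  graphics::segments(a[1], a[2], b[1], b[2], col = "grey30")
  draw_end <- function(pt, dir, m) {
    if (m == MARK_ARROW)
      graphics::arrows(pt[1] - dir[1] * 0.05, pt[2] - dir[2] * 0.05,
                       pt[1], pt[2], length = 0.08, col = "grey30")
    else if (m == MARK_CIRCLE)
      graphics::points(pt[1], pt[2], pch = 21, bg = "white", cex = 0.8,
                       col = "grey30")
  }
  draw_end(b, u, m2)
  draw_end(a, -u, m1)
}

#' @export
plot.anchorfci_fit <- function(x, ...) {
  plot.marked_graph(x$pag, highlight = x$anchors, ...)
}

#' @export
plot.rfci_fit <- function(x, ...) {
  plot.marked_graph(x$pag, ...)
}
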