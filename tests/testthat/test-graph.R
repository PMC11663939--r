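test_that("marked graphs validate their mark tables", {
  g <- marked_graph(c("A", "B"))
  expect_s3_class(g, "marked_graph")
  expect_error(marked_graph(c("A", "A")), "unique")
  ## half-edge: absent at one end only
  m <- matrix(0L, 2, 2); m[1, 2] <- 2L
  expect_error(marked_graph(c("A", "B"), m), "half-edge")
  expect_error(add_edge(g, "A", "Q", "tail", "arrowhead"), "Q")
  g <- add_edge(g, "A", "B", "tail", "arrowhead")
  expect_identical(g$amat["A", "B"], 2L)  # arrowhead at B
  expect_identical(g$amat["B", "A"], 3L)  # tail at A
})

test_that("m-separation follows ancestral-graph semantics on canonical motifs", {
  chain <- dag_from_arcs(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  expect_true(m_separated(chain, "A", "C", "B"))
  expect_false(m_separated(chain, "A", "C"))
  collider <- dag_from_arcs(c("A", "B", "C"), list(c("A", "C"), c("B", "C")))
  expect_false(m_separated(collider, "A", "B", "C"))
  expect_true(m_separated(collider, "A", "B"))
  ## descendant of a collider opens it
  dcol <- dag_from_arcs(c("A", "B", "C", "D"),
                        list(c("A", "C"), c("B", "C"), c("C", "D")))
  expect_false(m_separated(dcol, "A", "B", "D"))
  expect_error(m_separated(chain, "A", "Z"), "Z")
  expect_error(m_separated(chain, "A", "C", "A"), "must not be in Z")
})

test_that("m-separation agrees with exhaustive path enumeration on random MAGs", {
  for (s in 1:20) {
    mg <- random_test_mag(n_obs = 6, n_latent = 1, seed = s)$mag
    nodes <- mg$labels
    for (x in nodes) for (y in nodes) {
      if (x >= y) next
      others <- setdiff(nodes, c(x, y))
      for (k in 0:min(3, length(others))) {
        for (Z in combn(others, k, simplify = FALSE)) {
          expect_identical(m_separated(mg, x, y, Z), bf_m_separated(mg, x, y, Z),
                           info = sprintf("seed %d: %s _||_ %s | {%s}",
                                          s, x, y, paste(Z, collapse = ",")))
        }
      }
    }
  }
})

test_that("ancestral validity detects cycles, almost-cycles and selection edges", {
  dagg <- dag_from_arcs(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  expect_true(is_valid_ancestral(dagg))
  almost <- graph_from_edges(c("A", "B"),
                             list(list("A", "B", "tail", "arrowhead"),
                                  list("A", "B", "arrowhead", "arrowhead")))
  ## one edge slot per pair: re-adding replaces, so construct via two pairs
  almost <- graph_from_edges(c("A", "B", "C"),
                             list(list("A", "B", "tail", "arrowhead"),
                                  list("B", "C", "tail", "arrowhead"),
                                  list("A", "C", "arrowhead", "arrowhead")))
  ## A -> B -> C and A <-> C: directed path A..C plus bidirected edge
  ok <- is_valid_ancestral(almost)
  expect_false(ok)
  expect_true(any(grepl("almost", vapply(attr(ok, "violations"), paste,
                                         "", collapse = " "))))
  cyc <- graph_from_edges(c("A", "B", "C"),
                          list(list("A", "B", "tail", "arrowhead"),
                               list("B", "C", "tail", "arrowhead"),
                               list("C", "A", "tail", "arrowhead")))
  ok2 <- is_valid_ancestral(cyc)
  expect_false(ok2)
  sel <- graph_from_edges(c("A", "B"), list(list("A", "B", "tail", "tail")))
  expect_false(is_valid_ancestral(sel))
})

test_that("latent projection marginalizes confounders correctly", {
  conf <- dag_from_arcs(c("A", "B", "L"), list(c("L", "A"), c("L", "B")))
  mag <- latent_project(conf, "L")
  expect_identical(mag$amat["A", "B"], 2L)
  expect_identical(mag$amat["B", "A"], 2L)  # A <-> B
  ## no latents: same edges, directed marks
  dagg <- dag_from_arcs(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  same <- latent_project(dagg, character())
  expect_identical(same$amat, dagg$amat)
  cyc <- graph_from_edges(c("A", "B"), list(list("A", "B", "arrowhead", "arrowhead")))
  expect_error(latent_project(cyc, character()), "directed")
})

test_that("projected MAGs entail exactly the observed d-separations of the DAG", {
  for (s in 1:10) {
    sysg <- random_test_mag(n_obs = 5, n_latent = 2, seed = 100 + s)
    mag <- sysg$mag
    expect_true(is_valid_ancestral(mag))
    obs <- sysg$obs
    for (x in obs) for (y in obs) {
      if (x >= y) next
      others <- setdiff(obs, c(x, y))
      for (k in 0:min(3, length(others)))
        for (Z in combn(others, k, simplify = FALSE))
          expect_identical(m_separated(mag, x, y, Z),
                           m_separated(sysg$dag, x, y, Z),
                           info = sprintf("seed %d: %s,%s | %s", s, x, y,
                                          paste(Z, collapse = ",")))
    }
  }
})

test_that("structural Hamming distance counts adjacency and endpoint marks", {
  g1 <- graph_from_edges(c("A", "B"), list(list("A", "B", "circle", "circle")))
  g2 <- graph_from_edges(c("A", "B"), list(list("A", "B", "circle", "arrowhead")))
  expect_identical(shd(g1, g1), 0L)
  expect_identical(shd(g1, g2), 1L)
  empty <- marked_graph(c("A", "B"))
  expect_identical(shd(g1, empty), 1L)
  expect_error(shd(g1, marked_graph(c("A", "Q"))), "labels")
  ## metric properties on random graph triples
  rand_pag <- function(seed) {
    set.seed(seed)
    g <- marked_graph(LETTERS[1:4])
    for (i in 1:3) for (j in (i + 1):4) {
      if (runif(1) < 0.6) {
        g$amat[i, j] <- sample(1:3, 1)
        g$amat[j, i] <- sample(1:3, 1)
      }
    }
    g
  }
  for (s in 1:10) {
    a <- rand_pag(3 * s); b <- rand_pag(3 * s + 1); c <- rand_pag(3 * s + 2)
    expect_identical(shd(a, b), shd(b, a))
    expect_identical(shd(a, a), 0L)
    expect_lte(shd(a, c), shd(a, b) + shd(b, c))
  }
})

test_that("a misoriented conservative run sits at distance five from the true PAG", {
  sys <- worked_mag_system()
  truth <- true_pag(sys$mag)
  misrun <- worked_unfaithful_rfci_pag()
  expect_identical(shd(misrun, truth), 5L)
})

test_that("possible descendants match enumeration of possibly-directed paths", {
  chain <- dag_from_arcs(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  expect_setequal(possible_descendants(chain, "A"), c("A", "B", "C"))
  expect_setequal(possible_descendants(chain, "C"), "C")
  for (s in 1:10) {
    set.seed(400 + s)
    g <- marked_graph(LETTERS[1:5])
    for (i in 1:4) for (j in (i + 1):5) if (runif(1) < 0.5) {
      g$amat[i, j] <- sample(1:3, 1); g$amat[j, i] <- sample(1:3, 1)
    }
    for (x in g$labels)
      expect_identical(sort(possible_descendants(g, x)),
                       bf_possible_descendants(g, x))
  }
})

test_that("definite-status paths and their openness are classified correctly", {
  fork <- dag_from_arcs(c("X", "C", "Y"), list(c("C", "X"), c("C", "Y")))
  st <- definite_status_open(fork, c("X", "C", "Y"))
  expect_true(st$definite_status); expect_true(st$open)
  st2 <- definite_status_open(fork, c("X", "C", "Y"), "C")
  expect_false(st2$open)
  coll <- dag_from_arcs(c("X", "C", "Y"), list(c("X", "C"), c("Y", "C")))
  st3 <- definite_status_open(coll, c("X", "C", "Y"))
  expect_true(st3$definite_status); expect_false(st3$open)
  expect_true(definite_status_open(coll, c("X", "C", "Y"), "C")$open)
  ## circles on both path edges with adjacent endpoints: not definite status
  amb <- graph_from_edges(c("X", "C", "Y", "W"),
                          list(list("X", "C", "circle", "circle"),
                               list("C", "Y", "circle", "circle"),
                               list("X", "Y", "circle", "circle")))
  st4 <- definite_status_open(amb, c("X", "C", "Y"))
  expect_false(st4$definite_status)
  expect_true(is.na(st4$open))
  expect_error(definite_status_open(fork, c("X", "Y")), "not a path|not adjacent")
})
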