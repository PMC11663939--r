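test_that("the stable skeleton removes edges with minimal sepsets under the oracle", {
  chain <- dag_from_arcs(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  sk <- stable_skeleton(oracle_ci_tester(chain), c("A", "B", "C"))
  expect_false(is_adjacent(sk$graph, 1, 3))
  expect_true(is_adjacent(sk$graph, 1, 2))
  got <- get(paste(sort(c("A", "C")), collapse = "\r"), envir = sk$sepsets)
  expect_identical(got$S, "B")
})

test_that("the skeleton is order-independent", {
  sys <- toy_anchor_system()
  tester <- oracle_ci_tester(sys$mag)
  nodes <- sys$mag$labels
  sk1 <- stable_skeleton(tester, nodes)
  set.seed(5)
  perm <- sample(nodes)
  sk2 <- stable_skeleton(tester, perm)
  expect_identical(sk1$graph$amat[nodes, nodes] != 0,
                   sk2$graph$amat[nodes, nodes] != 0)
  ## full fits agree too
  f1 <- rfci(tester = tester, nodes = nodes)
  f2 <- rfci(tester = tester, nodes = perm)
  expect_identical(f1$pag$amat[nodes, nodes], f2$pag$amat[nodes, nodes])
})

test_that("a forbidden-test filter suppresses exactly those queries", {
  sys <- toy_anchor_system()
  filt <- anchor_skeleton_filter(sys$roles)
  t_plain <- recording_tester(oracle_ci_tester(sys$mag))
  stable_skeleton(t_plain, sys$mag$labels)
  n_plain <- length(t_plain$qlog$queries)
  t_filt <- recording_tester(oracle_ci_tester(sys$mag))
  stable_skeleton(t_filt, sys$mag$labels, filter = filt)
  n_filt <- length(t_filt$qlog$queries)
  expect_lte(n_filt, n_plain)
  forbidden <- vapply(t_filt$qlog$queries, function(q)
    isTRUE(filt(q$i, q$j, q$S)), TRUE)
  expect_false(any(forbidden))
})

test_that("retention never removes edges under a faithful oracle", {
  for (s in 1:5) {
    mg <- random_test_mag(n_obs = 6, n_latent = 1, seed = 500 + s)$mag
    tester <- oracle_ci_tester(mg)
    sk <- stable_skeleton(tester, mg$labels)
    rt <- rfci_triple_retention(sk$graph, sk$sepsets, tester)
    expect_length(rt$removed, 0)
  }
})

test_that("retention removes a spurious edge the skeleton could not reach", {
  ## scripted unfaithful case: J _||_ K holds only given W, but W loses its
  ## edges to both J and K at level 0, so the adjacency-subset search never
  ## conditions on it; the triple check given sepset(I, J) = {W} finds it
  labels <- c("I", "K", "J", "W")
  script <- list(
    "J|W|" = 1, "K|W|" = 1,   # W disconnects from J and K marginally
    "I|J|W" = 1,              # removes I - J with sepset {W}
    "J|K|W" = 1               # the unfaithful independence, via W only
  )
  tester <- scripted_tester(labels, script)
  sk <- stable_skeleton(tester, labels)
  expect_true(is_adjacent(sk$graph, 2, 3))   # K - J survived the skeleton
  rt <- rfci_triple_retention(sk$graph, sk$sepsets, tester)
  expect_false(is_adjacent(rt$graph, 2, 3))
  got <- get(paste(sort(c("J", "K")), collapse = "\r"), envir = rt$sepsets)
  expect_identical(got$S, "W")   # shrinking keeps the needed element
})

test_that("stored sepsets are minimal under the oracle", {
  for (s in 1:5) {
    mg <- random_test_mag(n_obs = 6, n_latent = 1, seed = 600 + s)$mag
    tester <- oracle_ci_tester(mg)
    sk <- stable_skeleton(tester, mg$labels)
    rt <- rfci_triple_retention(sk$graph, sk$sepsets, tester)
    for (rec in anchorfci:::sepset_dump(rt$sepsets)) {
      expect_true(m_separated(mg, rec$x, rec$y, rec$sepset))
      for (z in rec$sepset)
        expect_false(m_separated(mg, rec$x, rec$y, setdiff(rec$sepset, z)),
                     info = sprintf("seed %d, %s-%s minus %s", s, rec$x,
                                    rec$y, z))
    }
  }
})

test_that("majority-rule classification votes over separating sets", {
  ## oracle collider: q = 0
  coll <- dag_from_arcs(c("A", "B", "C"), list(c("A", "C"), c("B", "C")))
  tester <- oracle_ci_tester(coll)
  sk <- stable_skeleton(tester, coll$labels)
  tt <- classify_triples(sk$graph, sk$sepsets, tester)
  expect_identical(tt$status, "collider")
  expect_equal(tt$q, 0)
  ## oracle chain: q = 1, non-collider
  chain <- dag_from_arcs(c("A", "B", "C"), list(c("A", "B"), c("B", "C")))
  t2 <- oracle_ci_tester(chain)
  sk2 <- stable_skeleton(t2, chain$labels)
  tt2 <- classify_triples(sk2$graph, sk2$sepsets, t2)
  expect_identical(tt2$status, "noncollider")
  expect_equal(tt2$q, 1)
})

test_that("a two-of-four vote is a tie and stays ambiguous", {
  ## adj(A)\{B} = {K, U, V}; adj(B)\{A} = {K}; exactly four separating
  ## sets, two containing K
  labels <- c("A", "K", "B", "U", "V")
  edges <- list(list("A", "K", "circle", "circle"),
                list("K", "B", "circle", "circle"),
                list("A", "U", "circle", "circle"),
                list("A", "V", "circle", "circle"))
  g <- graph_from_edges(labels, edges)
  script <- list("A|B|K" = 1, "A|B|K,U" = 1, "A|B|U" = 1, "A|B|V" = 1)
  tester <- scripted_tester(labels, script)
  store <- new.env(parent = emptyenv())
  assign(paste(sort(c("A", "B")), collapse = "\r"), list(S = "K", p = 1),
         envir = store)
  tt <- classify_triples(g, store, tester)
  row <- tt[tt$k == "K", ]
  expect_equal(row$q, 0.5)
  expect_identical(row$status, "ambiguous")
  expect_identical(row$n_sepsets, 4L)
})

test_that("v-structure orientation stamps colliders and skips ambiguity", {
  g <- graph_from_edges(c("A", "C", "B"),
                        list(list("A", "C", "circle", "circle"),
                             list("B", "C", "circle", "circle")))
  tt <- data.frame(i = "A", k = "C", j = "B", status = "collider", q = 0,
                   n_sepsets = 2L, stringsAsFactors = FALSE)
  out <- orient_v_structures(g, tt)
  expect_identical(out$amat["A", "C"], 2L)
  expect_identical(out$amat["B", "C"], 2L)
  expect_identical(out$amat["C", "A"], 1L)  # circles at the far ends stay
  tt$status <- "ambiguous"
  out2 <- orient_v_structures(g, tt)
  expect_identical(out2$amat, g$amat)
})

test_that("rule R1 orients definite non-collider continuations and is idempotent", {
  g <- graph_from_edges(c("A", "B", "C"),
                        list(list("A", "B", "tail", "arrowhead"),
                             list("B", "C", "circle", "circle")))
  tt <- data.frame(i = "A", k = "B", j = "C", status = "noncollider", q = 1,
                   n_sepsets = 1L, stringsAsFactors = FALSE)
  store <- new.env(parent = emptyenv())
  out <- apply_orientation_rules(g, tt, store)
  expect_identical(out$amat["B", "C"], 2L)  # arrowhead at C
  expect_identical(out$amat["C", "B"], 3L)  # tail at B
  again <- apply_orientation_rules(out, tt, store)
  expect_identical(again$amat, out$amat)
  ## ambiguous middle never drives R1
  tt$status <- "ambiguous"
  out2 <- apply_orientation_rules(g, tt, store)
  expect_identical(out2$amat["C", "B"], 1L)
})

test_that("the oracle pipeline is sound and self-consistent on random MAGs", {
  for (s in 1:10) {
    mg <- random_test_mag(n_obs = 6, n_latent = 1, seed = 700 + s)$mag
    fit <- rfci(tester = oracle_ci_tester(mg))
    again <- rfci(tester = oracle_ci_tester(mg))
    expect_identical(fit$pag$amat, again$pag$amat)
    ## skeleton equals the MAG's, and invariant marks agree with the MAG
    expect_identical(fit$pag$amat != 0, mg$amat != 0)
    inv <- fit$pag$amat %in% c(2L, 3L) & mg$amat != 0
    expect_identical(fit$pag$amat[inv], mg$amat[inv])
    expect_length(fit$conflicts, 0)
  }
})
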