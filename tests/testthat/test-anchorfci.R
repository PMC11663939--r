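test_that("variable roles must partition the columns", {
  expect_error(variable_roles(character()), "at least one")
  expect_error(variable_roles("A", "A"), "disjoint")
  expect_error(variable_roles("A", "G", c("G")), "disjoint")
  r <- variable_roles(c("A", "B"), "G1", "sex")
  expect_s3_class(r, "variable_roles")
})

test_that("the adapted skeleton filter forbids exactly anchor-anchor-on-interest", {
  roles <- variable_roles(c("A", "B"), c("G1", "G2", "G3"))
  f <- anchor_skeleton_filter(roles)
  expect_true(f("G1", "G2", "A"))
  expect_false(f("G1", "A", "B"))
  expect_false(f("G1", "G2", "G3"))
  expect_false(f("G1", "G2", character()))
  expect_true(f("G1", "G2", c("G3", "B")))
})

test_that("screening separates associated from independent candidates", {
  set.seed(41)
  n <- 2000
  g1 <- rbinom(n, 2, 0.4)            # strong effect on A
  g2 <- rbinom(n, 2, 0.4)            # independent of everything
  a <- 0.8 * g1 + rnorm(n)
  d <- data.frame(G1 = g1, G2 = g2, A = a)
  types <- c(G1 = "multinomial", G2 = "multinomial", A = "continuous")
  roles <- variable_roles("A", c("G1", "G2"))
  tester <- mixed_ci_tester(d, types)
  sc <- screen_anchor_candidates(tester, roles, alpha_screen = 1e-5)
  expect_true(sc$screened[sc$candidate == "G1"])
  expect_false(sc$screened[sc$candidate == "G2"])
  ## null candidate fails across seeds
  fails <- mean(vapply(1:30, function(s) {
    set.seed(2000 + s)
    dd <- data.frame(G = rbinom(500, 2, 0.4), A = rnorm(500))
    tt <- mixed_ci_tester(dd, c(G = "multinomial", A = "continuous"))
    !screen_anchor_candidates(tt, variable_roles("A", "G"), 1e-5)$screened
  }, TRUE))
  expect_gte(fails, 0.99)
  ## alpha_screen = 1 admits everyone
  sc1 <- screen_anchor_candidates(tester, roles, alpha_screen = 1)
  expect_true(all(sc1$screened))
})

test_that("reliable-anchor selection demands adjacency and unambiguity", {
  sys <- toy_anchor_system()
  tester <- oracle_ci_tester(sys$mag)
  sk <- stable_skeleton(tester, sys$mag$labels)
  tt <- classify_triples(sk$graph, sk$sepsets, tester)
  sel <- select_reliable_anchors(sk$graph, tt, sys$roles)
  expect_setequal(sel, c("G1", "G2", "G3"))
  ## candidate not adjacent to any interest variable is dropped
  lone <- marked_graph(c("G1", "A"))
  tt0 <- classify_triples(lone, new.env(parent = emptyenv()),
                          oracle_ci_tester(lone))
  expect_length(select_reliable_anchors(lone, tt0,
                                        variable_roles("A", "G1")), 0)
  ## one ambiguous triple disqualifies
  tt_amb <- tt
  hit <- which(tt_amb$i == "G1" | tt_amb$k == "G1" | tt_amb$j == "G1")[1]
  tt_amb$status[hit] <- "ambiguous"
  expect_false("G1" %in% select_reliable_anchors(sk$graph, tt_amb, sys$roles))
})

test_that("arrowhead enforcement stamps interest endpoints only", {
  roles <- variable_roles(c("A", "B"), c("G1", "G2"))
  g <- graph_from_edges(c("G1", "G2", "A", "B"),
                        list(list("G1", "A", "circle", "circle"),
                             list("G2", "A", "circle", "arrowhead"),
                             list("G1", "G2", "circle", "circle"),
                             list("A", "B", "circle", "circle")))
  out <- enforce_anchor_arrowheads(g, c("G1", "G2"), roles)
  expect_identical(out$amat["G1", "A"], 2L)       # G1 o-> A
  expect_identical(out$amat["A", "G1"], 1L)       # anchor mark untouched
  expect_identical(out$amat["G2", "A"], 2L)       # already oriented: unchanged
  expect_identical(out$amat["G1", "G2"], 1L)      # anchor-anchor unaffected
  expect_identical(out$amat["A", "B"], 1L)        # interest pair unaffected
  ## a tail at the interest endpoint contradicts the partial order
  bad <- add_edge(g, "G1", "A", "circle", "tail")
  expect_error(enforce_anchor_arrowheads(bad, "G1", roles),
               "non-ancestral knowledge violated")
})

test_that("anchored discovery on the worked oracle recovers the narrative marks", {
  sys <- toy_anchor_system()
  fit <- anchorfci(tester = oracle_ci_tester(sys$mag), roles = sys$roles)
  a <- fit$pag$amat
  expect_setequal(fit$anchors, c("G1", "G2", "G3"))
  ## anchor edges oriented into the interest set, circles at the anchors
  expect_identical(a["G1", "A"], 2L); expect_identical(a["A", "G1"], 1L)
  expect_identical(a["G2", "D"], 2L); expect_identical(a["D", "G2"], 1L)
  expect_identical(a["G3", "B"], 2L); expect_identical(a["B", "G3"], 1L)
  ## tails learned beyond the equivalence class
  expect_identical(a["C", "A"], 3L); expect_identical(a["A", "C"], 2L)  # A -> C
  expect_identical(a["C", "B"], 3L); expect_identical(a["B", "C"], 2L)  # B -> C
  ## collider at E between C and B
  expect_identical(a["C", "E"], 2L)
  expect_identical(a["B", "E"], 2L)
})

test_that("without anchors the fit degenerates to the plain engine", {
  sys <- toy_anchor_system()
  interest_mag <- latent_project(sys$dag, c(sys$latent, "G1", "G2", "G3"))
  roles <- variable_roles(sys$roles$interest)
  fit_a <- anchorfci(tester = oracle_ci_tester(interest_mag), roles = roles)
  fit_r <- rfci(tester = oracle_ci_tester(interest_mag))
  expect_identical(fit_a$pag$amat, fit_r$pag$amat)
  expect_length(fit_a$anchors, 0)
})

test_that("the phase-2 filter only removes tests", {
  sys <- toy_anchor_system()
  t1 <- oracle_ci_tester(sys$mag)
  anchorfci(tester = t1, roles = sys$roles, screen_alpha = 1)
  ## an unfiltered second phase on the same nodes performs at least as many
  t_plain <- oracle_ci_tester(sys$mag)
  rfci(tester = t_plain)
  t_filt <- recording_tester(oracle_ci_tester(sys$mag))
  filt <- anchor_skeleton_filter(sys$roles)
  stable_skeleton(t_filt, sys$mag$labels, filter = filt)
  t_nofilt <- recording_tester(oracle_ci_tester(sys$mag))
  stable_skeleton(t_nofilt, sys$mag$labels)
  expect_lte(length(t_filt$qlog$queries), length(t_nofilt$qlog$queries))
})

test_that("no fit ever directs a definite edge from interest into an anchor", {
  for (s in 1:8) {
    sys <- random_anchored_mag(sim_config(), seed = 900 + s)
    fit <- anchorfci(tester = oracle_ci_tester(sys$mag), roles = sys$roles)
    a <- fit$pag$amat
    for (g in fit$anchors) for (v in sys$roles$interest) {
      if (a[g, v] == 0) next
      expect_false(a[v, g] == 2 && a[g, v] == 3,
                   info = sprintf("seed %d: %s -> %s", s, v, g))
    }
  }
})

test_that("bootstrap stability tallies edge types to unit mass", {
  set.seed(61)
  sys <- random_anchored_mag(sim_config(), seed = 12)
  dat <- simulate_mixed_data(sys, 400, seed = 5)
  types <- attr(dat, "types")
  st1 <- bootstrap_stability(dat, sys$roles, types, screen_alpha = 1,
                             B = 1, seed = 9)
  expect_true(all(st1$freq == 1))
  st <- bootstrap_stability(dat, sys$roles, types, screen_alpha = 1,
                            B = 5, seed = 9)
  sums <- tapply(st$freq, paste(st$x, st$y), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_lte(attr(st, "n_ok"), 5L)
})

test_that("a strong simulated edge is recovered in most bootstrap replicates", {
  set.seed(71)
  n <- 2500
  g <- rbinom(n, 2, 0.4)
  x <- 1.0 * g + rnorm(n)
  y <- 1.0 * x + rnorm(n)
  z <- 1.0 * y + rnorm(n)
  d <- data.frame(G = g, X = x, Y = y, Z = z)
  types <- c(G = "multinomial", X = "continuous", Y = "continuous",
             Z = "continuous")
  roles <- variable_roles(c("X", "Y", "Z"), "G")
  st <- bootstrap_stability(d, roles, types, screen_alpha = 1, B = 25,
                            seed = 31)
  xy <- st[st$x == "X" & st$y == "Y" & st$edge == "-->", ]
  expect_gte(if (nrow(xy)) xy$freq else 0, 0.8)
})
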