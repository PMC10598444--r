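test_that("wiring diagrams contain exactly the essential dependencies", {
  wd <- wiring_diagram(toy3())
  got <- paste(wd$edges$from, wd$edges$to, sep = "->")
  expect_setequal(got, c("x2->x1", "x3->x1", "x3->x2", "x1->x3", "x2->x3"))

  wd2 <- wiring_diagram(two_module_coupled())
  got2 <- paste(wd2$edges$from, wd2$edges$to, sep = "->")
  expect_setequal(got2, c("x2->x1", "x1->x2", "x1->y1", "x2->y1",
                          "y2->y1", "x2->y2", "y1->y2"))

  cst <- parse_rules(c("a, 1", "b, 0", "c, 1"))
  expect_equal(nrow(wiring_diagram(cst)$edges), 0L)

  ## external parameters are flagged as source-only nodes
  g <- parse_rules(c("# inputs: u", "a, u & b", "b, a"))
  wd3 <- wiring_diagram(g)
  expect_true(wd3$nodes$external[wd3$nodes$name == "u"])
})

test_that("SCC condensation yields the module DAG with stable ordering", {
  ## a strongly connected network is a single module
  dag1 <- strongly_connected_components(wiring_diagram(toy3()))
  expect_equal(length(dag1$module_vars), 1L)
  expect_setequal(dag1$module_vars[[1]], c("x1", "x2", "x3"))
  expect_true(dag1$non_trivial)

  dag2 <- strongly_connected_components(two_module_coupled())
  expect_equal(dag2$module_vars, list(c("x1", "x2"), c("y1", "y2")))
  expect_equal(nrow(dag2$edges), 1L)
  expect_equal(c(dag2$edges$from, dag2$edges$to), c(1L, 2L))

  ## edgeless diagram: all-trivial SCCs, empty Q
  cst <- parse_rules(c("a, 1", "b, 0", "c, 1", "d, 1", "e, 0"))
  dag3 <- strongly_connected_components(cst)
  expect_equal(length(dag3$module_vars), 5L)
  expect_false(any(dag3$non_trivial))
  expect_equal(nrow(dag3$edges), 0L)

  ## Q is acyclic: no back paths on random modular networks
  for (seed in 1:5) {
    net <- generate_modular_network(12, 3, 2, seed = seed)
    dag <- strongly_connected_components(net)
    expect_equal(length(dag$module_vars), 3L)
    g <- igraph::graph_from_data_frame(dag$edges, directed = TRUE,
      vertices = data.frame(name = seq_along(dag$module_vars)))
    expect_true(igraph::is_dag(g))
    expect_true(all(dag$edges$from < dag$edges$to))  # topological labels
  }
})

test_that("restriction keeps rules and declares outside regulators as inputs", {
  sub <- restriction(toy3(), c("x2", "x3"))
  expect_equal(sub$variables, c("x2", "x3"))
  expect_equal(sub$external, "x1")
  expect_equal(sub$rules$x2$tt, c(0L, 1L))          # x3
  expect_equal(sub$rules$x3$regulators, c("x1", "x2"))

  ## restriction to everything is the network itself
  all3 <- restriction(toy3(), c("x1", "x2", "x3"))
  expect_true(boolmod:::bn_equal(all3, toy3()))
  expect_equal(all3$external, character(0))

  ## downstream module of the coupled pair recovers G up to renaming
  sub2 <- restriction(two_module_coupled(), c("y1", "y2"))
  G <- parse_rules(c("# inputs: u1 u2",
                     "y1, u1 | (u2 & y2)", "y2, !u2 & y1"))
  renamed <- boolean_network(
    G$variables,
    lapply(G$rules, boolmod:::rename_regulators,
           map = c(u1 = "x1", u2 = "x2")),
    c("x1", "x2"))
  expect_true(boolmod:::bn_equal(sub2, renamed))

  expect_error(restriction(toy3(), character(0)), "non-empty")
  expect_error(restriction(toy3(), "zz"), "subset")
})

test_that("the semi-direct product substitutes coupled parameters", {
  F1 <- parse_rules(c("x1, x2", "x2, x1"))
  G <- parse_rules(c("# inputs: u1 u2",
                     "y1, u1 | (u2 & y2)", "y2, !u2 & y1"))
  H <- semidirect_product(F1, G, c(u1 = "x1", u2 = "x2"))
  expect_true(boolmod:::bn_equal(H, two_module_coupled()))
  expect_equal(H$external, character(0))

  ## the linear (XOR) variant
  G2 <- parse_rules(c("# inputs: u1 u2", "y1, u1 + u2 + y2", "y2, u2 + y1"))
  H2 <- semidirect_product(F1, G2, c(u1 = "x1", u2 = "x2"))
  H2ref <- parse_rules(c("x1, x2", "x2, x1",
                         "y1, x1 + x2 + y2", "y2, x2 + y1"))
  expect_true(boolmod:::bn_equal(H2, H2ref))

  ## empty coupling = cross product: disjoint union of wiring diagrams
  F2 <- parse_rules(c("x3, x4", "x4, x3"))
  X <- semidirect_product(F1, F2)
  wd <- wiring_diagram(X)
  expect_setequal(paste(wd$edges$from, wd$edges$to),
                  c("x2 x1", "x1 x2", "x4 x3", "x3 x4"))

  ## a partially mapped product keeps the leftover parameter external
  H3 <- semidirect_product(F1, G, c(u1 = "x1"))
  expect_equal(H3$external, "u2")

  expect_error(semidirect_product(F1, parse_rules(c("x1, x1"))), "collision")
  expect_error(semidirect_product(F1, G, c(u9 = "x1")), "external parameters")
  expect_error(semidirect_product(F1, G, c(u1 = "zz")), "variables")
})

test_that("structural decomposition is exact and round-trips bit-exactly", {
  d <- structural_decompose(two_module_coupled())
  expect_equal(length(d$modules), 2L)
  expect_equal(d$modules[[1]]$variables, c("x1", "x2"))
  expect_equal(d$modules[[2]]$variables, c("y1", "y2"))
  expect_equal(d$modules[[2]]$external, c("x1", "x2"))
  expect_equal(d$schemes[[1]], c(x1 = "x1", x2 = "x2"))

  ## strongly connected network: single module, no schemes
  d1 <- structural_decompose(toy3())
  expect_equal(length(d1$modules), 1L)
  expect_equal(length(d1$schemes), 0L)
  expect_true(boolmod:::bn_equal(recompose(d1), toy3()))

  ## property: generated modular networks round-trip exactly
  for (seed in 1:20) {
    m <- sample(1:3, 1)
    net <- generate_modular_network(12, m, 2, seed = seed)
    d2 <- structural_decompose(net)
    expect_equal(length(d2$modules), m)
    back <- recompose(d2)
    expect_identical(serialize_rules(back), serialize_rules(net))
  }
})

test_that("three-module bracketing is associative", {
  for (seed in 1:10) {
    net <- generate_modular_network(9, 3, 2, seed = 300 + seed)
    d <- structural_decompose(net)
    m1 <- d$modules[[1]]; m2 <- d$modules[[2]]; m3 <- d$modules[[3]]
    idmap <- function(params) setNames(params, params)
    ## right bracketing: F1 |x (F2 |x F3)
    inner <- semidirect_product(m2, m3,
      idmap(intersect(m3$external, m2$variables)))
    right <- semidirect_product(m1, inner,
      idmap(intersect(inner$external, m1$variables)))
    ## left bracketing: (F1 |x F2) |x F3
    outer <- semidirect_product(m1, m2,
      idmap(intersect(m2$external, m1$variables)))
    left <- semidirect_product(outer, m3,
      idmap(intersect(m3$external, outer$variables)))
    expect_true(boolmod:::bn_equal(left, right))
    expect_identical(serialize_rules(left), serialize_rules(right))
  }
})

test_that("module set is invariant under admissible reorderings", {
  ## modules computed from the network equal modules of the recomposition
  ## in any associative order (tested via decompose of the recomposed net)
  net <- generate_modular_network(12, 3, 2, seed = 77)
  d <- structural_decompose(net)
  nets2 <- recompose(d, reorder = FALSE)   # module-concatenated order
  d2 <- structural_decompose(nets2)
  key <- function(mod) paste(sort(mod$variables), collapse = ",")
  expect_setequal(vapply(d$modules, key, character(1)),
                  vapply(d2$modules, key, character(1)))
})
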