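test_that("input trajectories project upstream attractors onto coupled variables", {
  F1 <- parse_rules(c("x1, x2", "x2, x1"))
  A1 <- enumerate_attractors(F1)
  cyc <- A1$attractors[[which(vapply(A1$attractors, length, 1L) == 2L)]]
  g <- input_trajectory(cyc, c(u = "x2"), F1)
  expect_equal(g$period, 2L)
  expect_equal(as.integer(g$values[, "u"]), c(1L, 0L))  # (01, 10) -> x2 = 1, 0

  ## steady states give constant inputs
  g0 <- input_trajectory(boolmod:::new_attractor("00"), c(u = "x2"), F1)
  expect_equal(g0$period, 1L)
  expect_equal(as.integer(g0$values[, "u"]), 0L)
  g1 <- input_trajectory(boolmod:::new_attractor("11"), c(u = "x2"), F1)
  expect_equal(as.integer(g1$values[, "u"]), 1L)

  expect_error(input_trajectory(cyc, c(u = "zz"), F1), "upstream variable")
})

test_that("driven attractors match the worked two-module example", {
  ## downstream G = (u & x4, x3) under the three upstream attractors
  G <- parse_rules(c("# inputs: u", "x3, u & x4", "x4, x3"))
  F1 <- parse_rules(c("x1, x2", "x2, x1"))
  proj <- c(u = "x2")

  ## constant u = 0: the driven module collapses to its zero state
  pa0 <- nonautonomous_attractors(
    G, input_trajectory(boolmod:::new_attractor("00"), proj, F1))
  expect_equal(sort(vapply(pa0, function(p) paste(p$attractor$states,
    collapse = ","), character(1))), "00")

  ## constant u = 1: the driven module runs free, all three attractors
  pa1 <- nonautonomous_attractors(
    G, input_trajectory(boolmod:::new_attractor("11"), proj, F1))
  expect_equal(sort(vapply(pa1, function(p) paste(p$attractor$states,
    collapse = ","), character(1))), sort(c("00", "11", "01,10")))

  ## alternating drive from the 2-cycle: {00, (01, 10)}
  cyc <- boolmod:::new_attractor(c("01", "10"))
  pac <- nonautonomous_attractors(G, input_trajectory(cyc, proj, F1))
  expect_equal(sort(vapply(pac, function(p) paste(p$attractor$states,
    collapse = ","), character(1))), sort(c("00", "01,10")))

  ## unmapped parameters need explicit constants
  G2 <- parse_rules(c("# inputs: u v", "x3, u & x4", "x4, v & x3"))
  expect_error(nonautonomous_attractors(
    G2, input_trajectory(cyc, proj, F1)), "constants")
})

test_that("composed attractors have length lcm and sit in the full network", {
  full <- coupled4()
  aset <- enumerate_attractors(full)
  F1 <- parse_rules(c("x1, x2", "x2, x1"))
  G <- parse_rules(c("# inputs: u", "x3, u & x4", "x4, x3"))
  proj <- c(u = "x2")

  ## C1 = (01, 10) with driven 2-cycle: combined (0101, 1010), lcm(2,2) = 2
  cyc <- boolmod:::new_attractor(c("01", "10"))
  pac <- nonautonomous_attractors(G, input_trajectory(cyc, proj, F1))
  twoc <- pac[[which(vapply(pac, function(p) p$period, 1L) == 2L)]]
  comp <- compose_attractor(cyc, twoc, c("x1", "x2"), c("x3", "x4"))
  expect_equal(comp$states, c("0101", "1010"))
  expect_equal(length(comp$states),
               boolmod:::lcm2(2L, twoc$period))

  ## C1 = 11 steady with driven 2-cycle: combined (1101, 1110), lcm(1,2) = 2
  pa1 <- nonautonomous_attractors(
    G, input_trajectory(boolmod:::new_attractor("11"), proj, F1))
  twoc1 <- pa1[[which(vapply(pa1, function(p) p$period, 1L) == 2L)]]
  comp1 <- compose_attractor(boolmod:::new_attractor("11"), twoc1,
                             c("x1", "x2"), c("x3", "x4"))
  expect_equal(comp1$states, c("1101", "1110"))

  ## steady + steady composes to a steady state
  pa0 <- nonautonomous_attractors(
    G, input_trajectory(boolmod:::new_attractor("00"), proj, F1))
  comp0 <- compose_attractor(boolmod:::new_attractor("00"), pa0[[1]],
                             c("x1", "x2"), c("x3", "x4"))
  expect_equal(comp0$states, "0000")

  ## every composed attractor is a true attractor of the full network
  for (cmp in list(comp, comp1, comp0)) {
    expect_true(paste(cmp$states, collapse = ",") %in% set_keys(aset))
  }
})

test_that("dynamic decomposition reproduces exhaustive enumeration", {
  ## cross product: 10 attractors (4 steady, 6 cycles), the product law
  Fa <- cross4()
  ea <- enumerate_attractors(Fa)
  da <- dynamic_decompose(Fa)
  expect_equal(length(ea), 10L)
  expect_equal(set_keys(da), set_keys(ea))
  periods <- vapply(ea$attractors, length, 1L)
  expect_equal(sum(periods == 1L), 4L)

  ## coupled variant: only 6 of the 10 survive
  Fb <- coupled4()
  eb <- enumerate_attractors(Fb)
  db <- dynamic_decompose(Fb)
  expect_equal(length(eb), 6L)
  expect_equal(set_keys(db), set_keys(eb))

  ## strongly connected: identical to enumeration trivially
  expect_equal(set_keys(dynamic_decompose(toy3())),
               set_keys(enumerate_attractors(toy3())))

  ## agreement with the independent expression-level oracle
  keys <- oracle_attractor_keys(c(x1 = "x2", x2 = "x1",
                                  x3 = "x2 & x4", x4 = "x3"))
  expect_equal(set_keys_sorted(db), keys)
})

test_that("cross products obey the gcd phase-counting law", {
  ## |A(F1 x F2)| = sum over attractor pairs of gcd(|C1|, |C2|)
  combos <- list(
    list(c("x1, x2", "x2, x1"), c("x3, x4", "x4, x3")),
    list(c("x1, x2 & !x1", "x2, x1 | x2"), c("x3, !x4", "x4, x3")),
    list(c("x1, !x2", "x2, x1"), c("x3, x4", "x4, !x3"))
  )
  for (cmb in combos) {
    F1 <- parse_rules(cmb[[1]]); F2 <- parse_rules(cmb[[2]])
    prod <- semidirect_product(F1, F2)
    n_pairs <- 0L
    for (a1 in enumerate_attractors(F1)$attractors) {
      for (a2 in enumerate_attractors(F2)$attractors) {
        n_pairs <- n_pairs + boolmod:::gcd2(length(a1), length(a2))
      }
    }
    expect_equal(length(enumerate_attractors(prod)), n_pairs)
    expect_equal(length(dynamic_decompose(prod)), n_pairs)
  }
})

test_that("dynamic decomposition is bracketing-invariant on 3-module networks", {
  for (seed in 1:5) {
    net <- generate_modular_network(9, 3, 2, seed = 500 + seed)
    d <- structural_decompose(net)
    m1 <- d$modules[[1]]; m2 <- d$modules[[2]]; m3 <- d$modules[[3]]
    idmap <- function(p) setNames(p, p)
    inner <- semidirect_product(m2, m3,
      idmap(intersect(m3$external, m2$variables)))
    right <- semidirect_product(m1, inner,
      idmap(intersect(inner$external, m1$variables)))
    outer <- semidirect_product(m1, m2,
      idmap(intersect(m2$external, m1$variables)))
    left <- semidirect_product(outer, m3,
      idmap(intersect(m3$external, outer$variables)))
    ## compare in the original variable order so state strings align
    left <- boolmod:::reorder_variables(left, net$variables)
    right <- boolmod:::reorder_variables(right, net$variables)
    expect_equal(set_keys(dynamic_decompose(left)),
                 set_keys(dynamic_decompose(right)))
    expect_equal(set_keys(dynamic_decompose(left)),
                 set_keys(enumerate_attractors(net)))
  }
})
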