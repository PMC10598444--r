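test_that("control actions rewrite the network as specified", {
  net <- coupled4()   # (x2, x1, x2 & x4, x3)
  ## pinning x1 and x3 to 1 leaves a single steady state 1111
  mu <- list(control_action("node-constant", "x1", 1),
             control_action("node-constant", "x3", 1))
  ctl <- apply_controls(net, mu)
  aset <- enumerate_attractors(ctl)
  expect_equal(set_keys(aset), "1111")

  ## the empty control set changes nothing
  expect_true(boolmod:::bn_equal(apply_controls(net, list()), net))

  ## pinning every node forces exactly the pinned vector
  mu_all <- lapply(seq_along(net$variables), function(i)
    control_action("node-constant", net$variables[i], c(1, 0, 1, 0)[i]))
  expect_equal(set_keys(enumerate_attractors(apply_controls(net, mu_all))),
               "1010")

  ## edge deletion reads the source as constant 0 in the target rule only
  edel <- apply_controls(net, list(
    control_action("edge-deletion", "x3", source = "x2")))
  expect_equal(edel$rules$x3$tt, 0L)           # x2 & x4 with x2 := 0
  expect_equal(edel$rules$x1$regulators, "x2") # other rules untouched

  ## node deletion pins to 0 and substitutes 0 everywhere
  ndel <- apply_controls(net, list(
    control_action("node-deletion", "x4")))
  expect_equal(ndel$rules$x4$tt, 0L)
  expect_equal(ndel$rules$x3$tt, 0L)           # x2 & 0

  ## conflicting pins are refused
  expect_error(apply_controls(net, list(
    control_action("node-constant", "x1", 0),
    control_action("node-constant", "x1", 1))), "conflicting")
  expect_error(apply_controls(net, list(
    control_action("edge-deletion", "x1", source = "x3"))),
    "non-existent edge")
})

test_that("stabilization verification distinguishes success from failure", {
  net <- coupled4()
  mu <- list(control_action("node-constant", "x1", 1),
             control_action("node-constant", "x3", 1))
  expect_true(verify_stabilization(net, mu, "1111"))
  expect_true(verify_stabilization(net, mu, "1111", method = "exhaustive"))
  ## empty controls on a multi-attractor network
  expect_false(verify_stabilization(net, list(), "1111"))
  ## pinned values inconsistent with the target
  expect_false(verify_stabilization(net, mu, "0000"))
})

test_that("module controls compose to full-network controls", {
  net <- coupled4()
  d <- structural_decompose(net)
  res <- compose_module_controls(
    d,
    list(list(control_action("node-constant", "x1", 1)),
         list(control_action("node-constant", "x3", 1))),
    list("11", "11"))
  expect_true(res$verified)
  expect_equal(res$attractor$states, "1111")
  expect_equal(length(res$controls), 2L)
  expect_true(verify_stabilization(net, res$controls, res$attractor,
                                   method = "exhaustive"))

  ## single-module decomposition passes straight through
  d1 <- structural_decompose(toy3())
  res1 <- compose_module_controls(
    d1, list(list(control_action("node-constant", "x1", 0),
                  control_action("node-constant", "x2", 1),
                  control_action("node-constant", "x3", 1))),
    list("011"))
  expect_equal(res1$attractor$states, "011")

  ## two uncoupled modules with steady targets: union pins the product state
  prod <- cross4()
  dp <- structural_decompose(prod)
  resp <- compose_module_controls(
    dp,
    list(list(control_action("node-constant", "x1", 1),
              control_action("node-constant", "x2", 1)),
         list(control_action("node-constant", "x3", 0),
              control_action("node-constant", "x4", 0))),
    list("11", "00"))
  expect_equal(resp$attractor$states, "1100")

  ## the steady-state hypothesis is enforced: two cyclic targets refused
  expect_error(compose_module_controls(
    dp, list(list(), list()),
    list(boolmod:::new_attractor(c("01", "10")),
         boolmod:::new_attractor(c("01", "10")))),
    "do not stabilize|hypothesis")
})

test_that("the composition theorem holds on random 2-module networks", {
  ## for networks whose module targets satisfy the steady-state hypothesis,
  ## the union of module controls always stabilizes the full network
  tested <- 0L
  seed <- 0L
  while (tested < 15L && seed < 200L) {
    seed <- seed + 1L
    net <- generate_modular_network(8, 2, 2, seed = 7000 + seed)
    d <- structural_decompose(net)
    F1 <- d$modules[[1]]
    a1 <- enumerate_attractors(F1)
    steadies <- Filter(function(a) length(a$states) == 1L, a1$attractors)
    if (!length(steadies)) next
    C1 <- steadies[[1]]
    mu1 <- lapply(seq_along(F1$variables), function(i)
      control_action("node-constant", F1$variables[i],
                     boolmod:::string_to_bits(C1$states)[i]))
    ## driven module under the stabilized (constant) upstream input
    G <- d$modules[[2]]
    consts <- setNames(
      boolmod:::string_to_bits(C1$states)[match(G$external, F1$variables)],
      G$external)
    G0 <- pin_external(G, consts)
    ag <- enumerate_attractors(G0)
    if (length(ag$attractors) == 1L) {
      C2 <- ag$attractors[[1]]        # no downstream control needed
      mu2 <- list()
    } else {
      C2 <- ag$attractors[[1]]
      if (length(C2$states) > 1L) next   # keep the hypothesis satisfied
      mu2 <- lapply(seq_along(G$variables), function(i)
        control_action("node-constant", G$variables[i],
                       boolmod:::string_to_bits(C2$states)[i]))
    }
    res <- compose_module_controls(d, list(mu1, mu2), list(C1, C2))
    expect_true(res$verified)
    expect_true(verify_stabilization(net, res$controls, res$attractor,
                                     method = "exhaustive"))
    tested <- tested + 1L
  }
  expect_gte(tested, 15L)
})

test_that("minimal control search finds the smallest pinning sets", {
  net <- coupled4()
  hits <- search_minimal_controls(net, "1111", max_size = 2)
  expect_true(length(hits) >= 1L)
  expect_true(all(vapply(hits, length, 1L) == 2L))
  ## {x1 := 1, x3 := 1} is among the minimal solutions
  keys <- vapply(hits, function(set)
    paste(sort(vapply(set, function(a)
      paste0(a$target, ":=", a$value), character(1))), collapse = ","),
    character(1))
  expect_true("x1:=1,x3:=1" %in% keys)
  ## every returned set verifies on the full network
  for (set in hits) {
    expect_true(verify_stabilization(net, set, "1111",
                                     method = "exhaustive"))
  }
  ## an already-stable network needs no control
  cst <- parse_rules(c("a, 0", "b, a"))
  hits0 <- search_minimal_controls(cst, "00", max_size = 1)
  expect_equal(length(hits0[[1]]), 0L)
})
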