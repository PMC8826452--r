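test_that("initial heat is uniform over seeds present in the network", {
  net <- random_net(10, p = 0.3, seed = 2)
  s4 <- seed_set(net$nodes[1:4])
  h <- initial_heat(net, s4)
  expect_equal(unname(h$values[net$nodes[1:4]]), rep(0.25, 4))
  expect_equal(sum(h$values), 1)
  expect_equal(h$t, 0)

  s1 <- seed_set(net$nodes[7])
  h1 <- initial_heat(net, s1)
  expect_equal(unname(h1$values[net$nodes[7]]), 1)
  expect_equal(sum(h1$values != 0), 1L)

  # missing seeds are dropped with a warning and the rest renormalized
  sm <- seed_set(c(net$nodes[1:2], "absent_gene"))
  expect_warning(hm <- initial_heat(net, sm), "absent_gene")
  expect_equal(unname(hm$values[net$nodes[1:2]]), c(0.5, 0.5))

  expect_error(suppressWarnings(initial_heat(net, seed_set("nope"))),
               "no seed")
})

test_that("propagation matches closed forms", {
  net <- ppi_network(c("a", "b"), data.frame(from = "a", to = "b",
                                             confidence = 999L))
  lap <- build_laplacian(net, "binary")
  h0 <- heat_vector(c(a = 1, b = 0))

  expect_equal(propagate(lap, h0, 0)$values, h0$values)

  # eigenvalues of [[1,-1],[-1,1]] are 0 and 2: closed form at t = 0.5
  h <- propagate(lap, h0, 0.5)
  expect_equal(unname(h$values),
               c(0.5 * (1 + exp(-1)), 0.5 * (1 - exp(-1))),
               tolerance = 1e-12)
  expect_equal(h$t, 0.5)

  # connected 4-node path, large t: uniform limit 0.25
  pn <- path_net(4)
  lp <- build_laplacian(pn, "binary")
  hp <- propagate(lp, initial_heat(pn, seed_set(pn$nodes[1])), 1e4)
  expect_equal(unname(hp$values), rep(0.25, 4), tolerance = 1e-6)

  expect_error(propagate(lap, h0, -1), "nonnegative")
  expect_error(propagate(lap, heat_vector(c(a = 1, b = 0, c = 0)), 1),
               "dimension")
})

test_that("propagation conserves mass, stays nonnegative and is a semigroup", {
  for (s in 1:8) {
    set.seed(100 + s)
    n <- sample(5:60, 1)
    net <- random_net(n, p = runif(1, 0.05, 0.4), seed = 200 + s)
    lap <- build_laplacian(net)
    h0 <- random_heat(net, seed = 300 + s)
    t1 <- runif(1, 0, 5); t2 <- runif(1, 0, 5)

    h1 <- propagate(lap, h0, t1)
    expect_equal(sum(h1$values), 1, tolerance = 1e-9)
    expect_gte(min(h1$values), -1e-12)

    h12 <- propagate(lap, h1, t2)
    hsum <- propagate(lap, h0, t1 + t2)
    expect_lt(max(abs(h12$values - hsum$values)), 1e-8)
    expect_equal(h12$t, hsum$t)
  }
})

test_that("uniformization agrees with the dense spectral oracle", {
  for (s in 1:12) {
    set.seed(400 + s)
    n <- sample(4:80, 1)
    net <- random_net(n, p = runif(1, 0.05, 0.5), seed = 500 + s)
    lap <- build_laplacian(net)
    h0 <- random_heat(net, seed = 600 + s)
    t <- runif(1, 0, 10)
    got <- propagate(lap, h0, t)$values
    want <- spectral_propagate(net, h0$values, t)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("heat mass per connected component is constant in time", {
  net <- ppi_network(c("a", "b", "c", "d", "e"),
                     data.frame(from = c("a", "c"), to = c("b", "d"),
                                confidence = c(800L, 400L)))
  lap <- build_laplacian(net)
  h0 <- initial_heat(net, seed_set(c("a", "c")))
  comp <- component_labels(net)
  m0 <- tapply(h0$values, comp, sum)
  for (t in c(0.3, 2, 20)) {
    ht <- propagate(lap, h0, t)
    expect_equal(tapply(ht$values, comp, sum), m0, tolerance = 1e-12)
  }
})

test_that("maximum heat is non-increasing in time on connected graphs", {
  pn <- path_net(8)
  lap <- build_laplacian(pn)
  h <- initial_heat(pn, seed_set(pn$nodes[3]))
  peaks <- vapply(c(0, 0.5, 1, 2, 4, 8, 16), function(t)
    max(propagate(lap, h, t)$values), numeric(1))
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("stability stopping rule returns the first close-enough time", {
  solo <- ppi_network("only", data.frame(from = character(),
                                         to = character(),
                                         confidence = integer()))
  lap1 <- build_laplacian(solo)
  expect_warning(st <- propagate_until_stable(lap1, heat_vector(c(only = 1))),
                 "washed out")
  expect_true(st$converged)
  expect_equal(st$t, 0.1)
  expect_equal(unname(st$heat$values), 1)

  # two-node graph converges to the uniform pair and warns about washout
  net <- ppi_network(c("a", "b"), data.frame(from = "a", to = "b",
                                             confidence = 999L))
  lap <- build_laplacian(net, "binary")
  expect_warning(st2 <- propagate_until_stable(lap, heat_vector(c(a = 1, b = 0))),
                 "washed out")
  expect_true(st2$converged)
  expect_equal(unname(st2$heat$values), c(0.5, 0.5), tolerance = 1e-6)

  # heat never crosses components: {a-b} plus isolated {c}
  net3 <- ppi_network(c("a", "b", "c"),
                      data.frame(from = "a", to = "b", confidence = 999L))
  lap3 <- build_laplacian(net3, "binary")
  expect_warning(st3 <- propagate_until_stable(lap3,
                                               heat_vector(c(a = 1, b = 0, c = 0))),
                 "washed out")
  expect_equal(unname(st3$heat$values), c(0.5, 0.5, 0), tolerance = 1e-6)

  # a schedule too short to stabilize reports converged = FALSE
  pn <- path_net(12)
  lapp <- build_laplacian(pn)
  stp <- propagate_until_stable(lapp, initial_heat(pn, seed_set(pn$nodes[1])),
                                diffusion_config(t_schedule = c(0.1, 0.2)))
  expect_false(stp$converged)
  expect_equal(stp$t, 0.2)
})

test_that("candidate selection applies threshold, ordering and seed exclusion", {
  h <- heat_vector(c(a = 0.5, b = 2e-5, c = 1e-6))
  cfg <- diffusion_config()
  got <- select_candidates(h, cfg = cfg)
  expect_equal(got$gene, c("a", "b"))

  # seeds removed when exclude_seeds is on (the default)
  got2 <- select_candidates(h, seed_set("b"), cfg)
  expect_equal(got2$gene, "a")

  # threshold zero returns everything, ties broken lexicographically
  h3 <- heat_vector(c(z = 0.3, a = 0.3, m = 0.4))
  got3 <- select_candidates(h3, cfg = diffusion_config(heat_threshold = 0))
  expect_equal(got3$gene, c("m", "a", "z"))

  expect_warning(
    select_candidates(heat_vector(c(a = 1)), seed_set("a"), cfg),
    "no candidate")
})
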