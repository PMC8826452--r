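test_that("empirical p-value arithmetic is exact", {
  expect_identical(lhdriver:::empirical_pvalue(25, 500), 0.05)
  expect_identical(lhdriver:::empirical_pvalue(0, 500), 0)
  expect_identical(lhdriver:::empirical_pvalue(500, 500), 1)
  # optional pseudo-count estimator never returns 0
  expect_equal(lhdriver:::empirical_pvalue(0, 500, pseudo_count = TRUE),
               1 / 501)
})

test_that("permutation p-values are reproducible, order-invariant and tied-safe", {
  net <- random_net(40, p = 0.15, seed = 21)
  lap <- build_laplacian(net)
  seeds <- seed_set(net$nodes[1:5])
  h <- propagate(lap, initial_heat(net, seeds), 0.2)
  cand <- select_candidates(h, seeds, diffusion_config(heat_threshold = 0))
  cfg <- screen_config(n_permutations = 50L, rng_seed = 99L)

  p1 <- permutation_pvalues(lap, net, cand, 5L, 0.2, cfg)
  p2 <- permutation_pvalues(lap, net, cand, 5L, 0.2, cfg)
  expect_identical(p1, p2)  # bit-for-bit under a fixed rng_seed

  # multiples of 1/n_permutations in [0, 1]
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_true(all(abs(p1 * 50 - round(p1 * 50)) < 1e-12))

  # shuffling candidate rows does not change any gene's p-value
  shuf <- cand[rev(seq_len(nrow(cand))), ]
  p3 <- permutation_pvalues(lap, net, shuf, 5L, 0.2, cfg)
  expect_equal(p3[names(p1)], p1)

  # exact ties are not exceedances: at t = 0 a replicate containing the
  # candidate puts exactly 1/seed_size on it; with actual heat equal to
  # 1/seed_size the strict comparison never counts it
  cand_tie <- data.frame(gene = net$nodes[6:10], heat = 1 / 4)
  p_tie <- permutation_pvalues(lap, net, cand_tie, 4L, 0, cfg)
  expect_true(all(p_tie == 0))

  expect_error(permutation_pvalues(lap, net, cand, 41L, 0.2, cfg),
               "exceeds")
})

test_that("permutation replicates reuse the Laplacian", {
  net <- random_net(25, p = 0.2, seed = 31)
  lap <- build_laplacian(net)
  cand <- data.frame(gene = net$nodes[1:3], heat = 0.01)
  lhdriver:::reset_counters()
  invisible(permutation_pvalues(lap, net, cand, 4L, 0.5,
                                screen_config(n_permutations = 30L)))
  ct <- lhdriver:::get_counters()
  expect_identical(ct$propagations, 30L)
  expect_identical(ct$laplacian_builds, 0L)  # operator built before, reused
})

test_that("maximum association score picks the strongest seed edge", {
  net <- ppi_network(c("g", "r1", "r2", "x"),
                     data.frame(from = c("g", "g", "g"),
                                to = c("r1", "r2", "x"),
                                confidence = c(950L, 300L, 999L)))
  ref <- seed_set(c("r1", "r2"))
  expect_equal(max_association_score(net, "g", ref), 950L)
  # no edge to any reference gene
  expect_equal(max_association_score(net, "x", seed_set("r2")), 0L)
  # g in the reference: only edges to other reference genes count
  expect_equal(max_association_score(net, "g", seed_set(c("g", "r2"))), 300L)
  expect_error(max_association_score(net, "zz", ref), "not in network")
  # every gene adjacent to a seed with confidence c has MAS >= c
  expect_gte(max_association_score(net, "r1", seed_set(c("g", "x"))), 950L)
})

test_that("functional linkage is a cosine with zero-vector guard", {
  expect_equal(linkage(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(linkage(c(1, 0), c(0, 1)), 0)
  expect_equal(linkage(c(3, 4), c(4, 3)), 24 / 25)
  expect_equal(linkage(c(0, 0), c(1, 1)), 0)
  expect_error(linkage(c(1, 2), c(1, 2, 3)), "lengths differ")
  # symmetric kernel
  set.seed(7)
  a <- runif(10); b <- runif(10)
  expect_equal(linkage(a, b), linkage(b, a), tolerance = 1e-12)
})

test_that("maximum function score takes the best reference linkage", {
  profiles <- list(g = c(1, 0, 1), r1 = c(1, 0, 1), r2 = c(0, 1, 0))
  expect_equal(max_function_score("g", seed_set(c("r1", "r2")), profiles), 1)
  expect_equal(max_function_score("g", seed_set("r2"), profiles), 0)
  # the gene itself never serves as its own reference
  expect_error(max_function_score("g", seed_set("g"), profiles),
               "no usable reference")
})

test_that("the staged screen is monotone and respects vacuous cutoffs", {
  fx <- simulate_fixture(fixture_spec(n_nodes = 80L,
                                      modules = list(list(size = 12L,
                                                          p_in = 0.8,
                                                          conf_in = c(700L, 999L))),
                                      rng_seed = 5L),
                         levels = list(lv = 1L))
  net <- fx$network
  lap <- build_laplacian(net)
  seeds <- fx$seeds$lv
  st <- propagate_until_stable(lap, initial_heat(net, seeds),
                               benchmark_dcfg())
  cand <- select_candidates(st$heat, seeds, benchmark_dcfg())

  scfg <- screen_config(n_permutations = 100L, rng_seed = 11L)
  tab <- run_screen(cand, lap, net, seeds, fx$catalog, cfg = scfg, t = st$t)
  cn <- attr(tab, "counts")
  expect_true(all(diff(cn) <= 0))  # raw >= s1 >= s2 >= s3
  expect_true(all(tab$gene[tab$latent] %in% cand$gene))
  # MAS/MFS only computed for survivors of the previous stage
  expect_true(all(is.na(tab$mas[tab$p_value >= scfg$p_cutoff])))

  # vacuous cutoffs keep every candidate through every stage
  vac <- screen_config(n_permutations = 20L, p_cutoff = 1.1, mas_cutoff = 0L,
                       mfs_cutoff = 0, rng_seed = 11L)
  tabv <- run_screen(cand, lap, net, seeds, fx$catalog, cfg = vac, t = st$t)
  expect_equal(unname(attr(tabv, "counts")), rep(nrow(cand), 4))

  # p_cutoff = 0 empties the pipeline at stage one
  zero <- screen_config(n_permutations = 20L, p_cutoff = 0, rng_seed = 11L)
  tab0 <- run_screen(cand, lap, net, seeds, fx$catalog, cfg = zero, t = st$t)
  expect_equal(unname(attr(tab0, "counts"))[2:4], c(0, 0, 0))
})
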