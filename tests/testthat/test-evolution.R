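test_that("selection models enforce their parameter invariants", {
  expect_error(selection_model(1, sigma = 0.1), "target")
  expect_error(selection_model("stability-no-target",
                               target = rep(1L, 10)), "forbids")
  expect_error(selection_model("cycle", l_opt = 1), "l_opt")
  expect_error(selection_model("attractor-target"), "target")
  m <- selection_model("cycle", l_opt = 3)
  expect_identical(m$model_id, 2L)
  expect_identical(m$l_opt, 3L)
  expect_true(is.infinite(m$sigma))
})

test_that("fitness follows the selection regimes", {
  fp <- find_attractor(matrix(1L, 1, 1), 1L)       # fixed point (+1)
  cyc <- find_attractor(matrix(-1L, 1, 1), 1L)     # period-2 cycle

  no_target <- selection_model("stability-no-target")
  expect_equal(fitness(fp, no_target), 1)
  expect_equal(fitness(cyc, no_target), 0)

  # target variant: fixed point equal to the target has fitness 1
  tgt <- selection_model("stability-target", sigma = 0.1, target = 1L)
  expect_equal(fitness(fp, tgt), 1)
  expect_equal(fitness(cyc, tgt), 0)

  # d = 0.5 at sigma = 0.1 gives exp(-5)
  a10 <- structure(list(transient_length = 0L, length = 1L,
                        cycle = matrix(rep(c(1L, -1L), each = 5), 1),
                        is_fixed_point = TRUE), class = "grn_attractor")
  m10 <- selection_model("stability-target", sigma = 0.1,
                         target = rep(1L, 10))
  expect_equal(fitness(a10, m10), exp(-5))

  # model 2: only the optimal cycle length survives, fixed points excluded
  m2 <- selection_model("cycle", l_opt = 2)
  expect_equal(fitness(cyc, m2), 1)
  expect_equal(fitness(fp, m2), 0)

  # model 3: best state of the attractor sets the fitness
  m3 <- selection_model("attractor-target", sigma = 0.1, target = 1L)
  expect_equal(fitness(cyc, m3), 1)   # cycle visits the target itself
  expect_equal(fitness(fp, m3), 1)

  # model 4: flat fitness
  m4 <- selection_model("neutral")
  expect_equal(fitness(cyc, m4), 1)
  expect_equal(fitness(fp, m4), 1)
})

test_that("Wright-Fisher selection is fitness-proportional and size-conserving", {
  set.seed(41)
  nets <- array(sample(c(-1L, 1L), 4 * 4 * 10, replace = TRUE), c(4, 4, 10))
  pop <- make_pop(nets, rep(1L, 4))

  f <- rep(0, 10); f[7] <- 2
  sel <- wright_fisher_select(pop, f)
  expect_identical(sel$n, 10L)
  for (k in 1:10) expect_identical(sel$networks[, , k], nets[, , 7])

  # equal fitnesses: offspring counts are multinomial-uniform
  picks <- unlist(lapply(1:200, function(i) {
    s <- wright_fisher_select(pop, rep(1, 10))
    vapply(1:10, function(k) sum(vapply(1:10, function(j)
      identical(s$networks[, , j], nets[, , k]), NA)), 0L)
  }))
  # chi-square goodness of fit against uniform expectation
  obs <- colSums(matrix(picks, ncol = 10, byrow = TRUE))
  chi <- sum((obs - 200)^2 / 200)
  expect_lt(chi, qchisq(0.999, df = 9))

  # all-zero fitness: uniform rescue, population survives
  r <- wright_fisher_select(pop, rep(0, 10))
  expect_identical(r$n, 10L)
  expect_true(attr(r, "rescued"))
})

test_that("mutation flips mu entries per network in expectation", {
  set.seed(42)
  nets <- array(sample(c(-1L, 1L), 100 * 2000, replace = TRUE),
                c(10, 10, 2000))
  pop <- make_pop(nets, rep(1L, 10))

  expect_identical(mutate(pop, 0)$networks, nets)

  mut <- mutate(pop, 0.1)
  flips <- sum(mut$networks != nets)
  # Binomial(2e5, 1e-3): mean 200, sd ~ 14
  expect_gt(flips, 140)
  expect_lt(flips, 260)

  # sparse: zeros never mutate, rate mu/(c N^2) on the support
  G <- array(0L, c(10, 10, 2000))
  for (k in 1:50) G[, , k] <- sparse_regular_network(10, 2)
  for (k in 51:2000) G[, , k] <- G[, , ((k - 1) %% 50) + 1]
  spop <- make_pop(G, rep(1L, 10), sparse = TRUE)
  smut <- mutate(spop, 0.1)
  expect_true(all(smut$networks[G == 0L] == 0L))
  sflips <- sum(smut$networks != G)
  # support 4e4 entries at rate 0.1/(0.2*100) = 5e-3: mean 200, sd ~ 14
  expect_gt(sflips, 140)
  expect_lt(sflips, 260)
})

test_that("recombination segregates complementary halves of the rows", {
  set.seed(43)
  A <- random_network(10)
  # identical parents produce identical offspring
  same <- make_pop(array(rep(A, 2), c(10, 10, 2)), rep(1L, 10))
  rec <- recombine(same)
  expect_identical(rec$networks[, , 1], A)
  expect_identical(rec$networks[, , 2], A)

  # with one pair, each offspring row comes from exactly one parent and
  # the two offspring split the parents' rows complementarily
  B <- random_network(10)
  pair <- make_pop(array(c(A, B), c(10, 10, 2)), rep(1L, 10))
  rec <- recombine(pair)
  o1 <- rec$networks[, , 1]; o2 <- rec$networks[, , 2]
  from_a1 <- vapply(1:10, function(i) identical(o1[i, ], A[i, ]), NA)
  from_b1 <- vapply(1:10, function(i) identical(o1[i, ], B[i, ]), NA)
  expect_true(all(from_a1 | from_b1))
  expect_identical(sum(from_a1 & !from_b1), 5L)
  # complementarity: rows of o2 are the rows o1 did not take
  expect_true(all(vapply(1:10, function(i)
    identical(o2[i, ], if (from_a1[i]) B[i, ] else A[i, ]), NA)))

  expect_error(recombine(make_pop(array(1L, c(2, 2, 3)), c(1L, 1L))),
               "even")
})

test_that("evolution runs are seed-reproducible and conserve structure", {
  cfg <- evolution_config(n = 50, N = 6, generations = 40, z = 2,
                          seed = 123, scan_schedule = c(0, 20, 40))
  m <- selection_model("stability-no-target")
  e1 <- evolve(cfg, m)
  e2 <- evolve(cfg, m)
  expect_identical(e1$records, e2$records)
  expect_identical(e1$final, e2$final)

  # entries stay in {-1, +1} and sizes are conserved
  for (k in 1:2) {
    expect_identical(dim(e1$final[[k]]), c(6L, 6L, 50L))
    expect_true(all(e1$final[[k]] %in% c(-1L, 1L)))
  }
  # under 'no target', mean fitness equals stability exactly at every
  # generation (fixed points have fitness exactly 1, cycles exactly 0)
  expect_identical(e1$records$mean_fitness, e1$records$stability)
})

test_that("sparse evolution preserves the row support pattern", {
  cfg <- evolution_config(n = 40, N = 10, generations = 30, z = 1,
                          seed = 7, sparse = TRUE, degree = 2,
                          scan_schedule = c(0, 30))
  e <- evolve(cfg, selection_model("stability-no-target"))
  fin <- e$final[[1]]
  expect_true(all(fin %in% c(-1L, 0L, 1L)))
  # rows segregate whole: every row still has exactly `degree` non-zeros
  expect_true(all(apply(fin != 0L, c(1, 3), sum) == 2L))
})

test_that("selection models push the sign of autoregulation as expected", {
  # directional responses at modest scale
  cfg <- evolution_config(n = 200, N = 10, generations = 150, z = 3,
                          seed = 2024, scan_schedule = c(0, 150))
  up <- evolve(cfg, selection_model("stability-no-target"))
  expect_gt(max(up$set_mean$mean_p), 0.85)
  expect_gt(up$set_mean$stability[nrow(up$set_mean)], 0.9)

  down <- evolve(cfg, selection_model("cycle", l_opt = 2))
  expect_lt(down$set_mean$mean_p[nrow(down$set_mean)], 0.4)

  flat <- evolve(cfg, selection_model("neutral"))
  expect_lt(abs(mean(flat$set_mean$mean_p)), 0.65)
  expect_gt(mean(flat$set_mean$mean_p), 0.35)
})

test_that("the compiled engine matches the reference R loop directionally", {
  set.seed(77)
  pop <- founding_population(n = 30, N = 6)
  ref <- boolgrn:::evolve_population_r(pop, selection_model("stability-no-target"),
                                       generations = 25, mu = 0.1,
                                       recombination = TRUE)
  expect_equal(nrow(ref$records), 26)
  expect_gt(ref$records$stability[26], ref$records$stability[1])
  expect_gt(ref$records$mean_p[26], ref$records$mean_p[1])
  # same invariant as the engine: fitness == stability under 'no target'
  expect_identical(ref$records$mean_fitness, ref$records$stability)
})

test_that("founding composition is honoured at generation zero", {
  cfg <- evolution_config(n = 60, N = 10, generations = 5, z = 1,
                          seed = 55, p0 = 0.9, q0 = 0.9,
                          scan_schedule = c(0, 5))
  e <- evolve(cfg, selection_model("neutral"))
  expect_equal(e$records$mean_p[1], 0.9)
  expect_equal(e$records$mean_q[1], 0.9)
})
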