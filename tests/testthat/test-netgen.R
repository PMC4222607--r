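test_that("random states are uniform over {-1, +1}^N and seed-reproducible", {
  set.seed(1)
  s <- random_state(10)
  expect_length(s, 10)
  expect_true(all(s %in% c(-1L, 1L)))

  set.seed(5)
  a <- random_state(50)
  set.seed(5)
  expect_identical(random_state(50), a)

  set.seed(2)
  expect_lt(abs(mean(random_state(1e5))), 0.02)  # binomial SE ~ 0.003
})

test_that("random dense networks have balanced signs", {
  set.seed(3)
  W <- random_network(10)
  expect_identical(dim(W), c(10L, 10L))
  expect_true(all(W %in% c(-1L, 1L)))

  p_hat <- mean(replicate(2000, sign_autoregulation_p(random_network(10))))
  expect_lt(abs(p_hat - 0.5), 0.02)  # SE ~ 0.0035

  set.seed(11)
  a <- random_network(10)
  set.seed(11)
  expect_identical(random_network(10), a)
})

test_that("sign composition is exact and off-grid values error", {
  set.seed(4)
  W <- network_with_sign_composition(10, p = 1, q = 0.5)
  expect_identical(sum(diag(W) > 0), 10L)
  expect_identical(sum(W[row(W) != col(W)] > 0), 45L)

  W7 <- network_with_sign_composition(10, p = 0.7)
  expect_identical(sum(diag(W7) > 0), 7L)
  expect_equal(sign_autoregulation_p(W7), 0.7)

  expect_error(network_with_sign_composition(10, p = 0.55), "grid")
  expect_error(network_with_sign_composition(10, p = 0.5, q = 0.501), "grid")

  # requested (p, q) are measured back exactly for every grid point
  for (p in seq(0, 1, by = 0.1)) {
    W <- network_with_sign_composition(10, p, q = 0.4)
    expect_equal(sign_autoregulation_p(W), p)
    expect_equal(sign_offdiag_q(W), 0.4)
  }
})

test_that("pre-selected stable networks verify as stable", {
  set.seed(6)
  for (rep in 1:5) {
    sn <- stable_network(10)
    expect_true(is_stable(sn$network, sn$state))
    expect_gte(sn$attempts, 1)
  }
  # composition-constrained harvesting keeps the requested signs
  sn <- stable_network(10, p = 0.9, q = 0.5)
  expect_true(is_stable(sn$network, sn$state))
  expect_equal(sign_autoregulation_p(sn$network), 0.9)
  expect_equal(sign_offdiag_q(sn$network), 0.5)
})

test_that("rejection sampling respects its draw cap", {
  set.seed(8)
  # p = 0 networks are almost never stable; a tiny cap must error
  expect_error(boolgrn:::harvest_stable(10, 5, p = 0, q = 0.5,
                                        max_draws = 10, batch = 10),
               "exhausted")
})

test_that("engineered networks keep donor off-diagonal and get new diagonal", {
  set.seed(9)
  donor <- network_with_sign_composition(10, p = 0.1, q = 48 / 90)
  eng <- engineered_network(donor, diag_p = 0.9)
  expect_equal(sign_offdiag_q(eng), sign_offdiag_q(donor))
  off <- row(eng) != col(eng)
  expect_identical(eng[off], donor[off])
  expect_equal(sign_autoregulation_p(eng), 0.9)
})

test_that("sparse regular networks have exact degree and density", {
  set.seed(10)
  for (rep in 1:10) {
    G <- sparse_regular_network(10, degree = 2)
    expect_true(all(G %in% c(-1L, 0L, 1L)))
    expect_identical(unname(rowSums(G != 0L)), rep(2, 10))
    expect_identical(unname(colSums(G != 0L)), rep(2, 10))
    expect_equal(mean(G != 0L), 0.2)  # c = degree / N
  }
  G0 <- sparse_regular_network(10, degree = 2, allow_self_loops = FALSE)
  expect_identical(unname(diag(G0)), rep(0L, 10))

  # signs of the support are balanced
  set.seed(12)
  signs <- unlist(replicate(300, {
    G <- sparse_regular_network(10, 2)
    G[G != 0L]
  }, simplify = FALSE))
  expect_lt(abs(mean(signs > 0) - 0.5), 0.02)  # SE ~ 0.006 at 6000 draws
})

test_that("population setups give shared vs independent initial states", {
  set.seed(13)
  rnic <- init_population(n = 500, N = 10, mode = "RNIC")
  expect_identical(rnic$n, 500L)
  expect_length(rnic$state, 10)
  expect_null(rnic$states)

  rnrc <- init_population(n = 200, N = 10, mode = "RNRC")
  expect_identical(dim(rnrc$states), c(10L, 200L))
  # independent states: mean pairwise normalized Hamming distance ~ 0.5
  d <- sapply(2:200, function(k)
    hamming_normalized(rnrc$states[, 1], rnrc$states[, k]))
  expect_lt(abs(mean(d) - 0.5), 0.05)
})

test_that("founding populations carry the requested composition", {
  set.seed(14)
  pop <- founding_population(n = 100, N = 10, p0 = 0.9, q0 = 0.9)
  ps <- apply(pop$networks, 3, sign_autoregulation_p)
  qs <- apply(pop$networks, 3, sign_offdiag_q)
  expect_true(all(ps == 0.9))
  expect_true(all(qs == 0.9))
  expect_length(pop$state, 10)

  dflt <- founding_population(n = 400, N = 10)
  expect_lt(abs(mean(apply(dflt$networks, 3, sign_autoregulation_p)) - 0.5),
            0.05)
})
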