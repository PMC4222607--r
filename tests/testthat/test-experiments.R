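# Small-scale versions of the figure-level recipes; the full-scale
# quantitative checks live in test-acceptance.R.

test_that("stability rises steeply with the sign of autoregulation", {
  set.seed(101)
  sv <- run_stability_vs_p(n_per_bin = 500)
  expect_identical(nrow(sv$bins), 11L)
  expect_identical(sv$bins$n_stable + (sv$bins$n - sv$bins$n_stable),
                   sv$bins$n)
  expect_gt(sv$bins$stability[11], 10 * max(sv$bins$stability[1], 1e-3))
  expect_gt(sv$median_p_stable, sv$median_p_unstable)
})

test_that("mutant scans of stable non-evolved networks respond to p", {
  set.seed(102)
  rv <- run_robustness_vs_p(stable_only = TRUE, q = 0.5, n_per_bin = 50,
                            p_grid = c(0.2, 0.6, 1))
  expect_true(all(rv$per_network$robustness >= 0 &
                  rv$per_network$robustness <= 1, na.rm = TRUE))
  expect_true(all(rv$per_network$viability >= 0 &
                  rv$per_network$viability <= 1))
  bp <- rv$by_p[order(rv$by_p$p), ]
  # mutant viability and the unconditional preserved-phenotype fraction
  # both rise with the sign of autoregulation
  expect_gt(bp$mean_viability[3], bp$mean_viability[1])
  expect_gt(bp$mean_fraction_same[3], bp$mean_fraction_same[1])
  expect_true(all(rv$by_robustness$mean_p >= 0 &
                  rv$by_robustness$mean_p <= 1))
})

test_that("time courses aggregate a set of populations", {
  cfg <- evolution_config(n = 100, N = 10, generations = 60, z = 2,
                          seed = 303, scan_schedule = c(0, 30, 60))
  evo <- run_timecourse(selection_model("stability-no-target"), cfg)
  expect_s3_class(evo, "grn_evolution")
  expect_identical(nrow(evo$set_mean), 61L)
  expect_identical(nrow(evo$scan_mean), 3L)
  expect_true(all(evo$set_mean$stability >= 0 & evo$set_mean$stability <= 1))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(evo))
})

test_that("diagonal mutants are more destabilising than off-diagonal ones", {
  set.seed(104)
  cfg <- evolution_config(n = 200, N = 10, generations = 300, z = 2,
                          seed = 304, scan_schedule = c(0, 300))
  evo <- evolve(cfg, selection_model("stability-no-target"))
  mp <- run_mutant_position_analysis(evo)
  expect_true(all(c("viability", "diag_viability", "offdiag_viability")
                  %in% names(mp$per_network)))
  expect_gt(mp$summary$median_offdiag_viability,
            mp$summary$median_diag_viability)
  expect_identical(dim(mp$heatmap), c(10L, 10L))
  # heat map: diagonal band less viable than off-diagonal background
  expect_lt(mean(diag(mp$heatmap)),
            mean(mp$heatmap[row(mp$heatmap) != col(mp$heatmap)]))
})

test_that("autoregulatory signs are conserved more than off-diagonal ones", {
  cfg <- evolution_config(n = 200, N = 10, generations = 500, z = 3,
                          seed = 305, scan_schedule = c(0, 100, 500))
  nt <- evolve(cfg, selection_model("stability-no-target"))
  cons_nt <- run_conservation_analysis(nt, 100, 500)
  expect_identical(c(cons_nt$t1, cons_nt$t2), c(100L, 500L))
  expect_true(all(cons_nt$matrix >= 0 & cons_nt$matrix <= 1))
  expect_gt(cons_nt$diag_median, cons_nt$offdiag_median)

  neu <- evolve(cfg, selection_model("neutral"))
  cons_neu <- run_conservation_analysis(neu, 100, 500)
  expect_gt(cons_nt$diag_median, cons_neu$diag_median)

  expect_error(run_conservation_analysis(nt, 500, 500), "distinct")
})

test_that("interaction strength of evolved sets is highest on the diagonal", {
  cfg <- evolution_config(n = 150, N = 10, generations = 200, z = 2,
                          seed = 306, scan_schedule = c(0, 200))
  evo <- evolve(cfg, selection_model("stability-no-target"))
  o <- interaction_strength(evo$final)
  expect_gt(mean(diag(o)), mean(o[row(o) != col(o)]))
})

test_that("engineered networks beat matched stable controls", {
  set.seed(107)
  ec <- run_engineered_comparison(n_per_group = 150)
  s <- ec$summary
  expect_identical(sort(s$group), c("control", "engineered"))
  eng <- s[s$group == "engineered", ]
  ctl <- s[s$group == "control", ]
  expect_gt(eng$median_robustness, ctl$median_robustness)
  # r lives on a 1/45 lattice, so group medians can tie at this scale;
  # the distribution shift shows in the mean and the median never reverses
  expect_gte(eng$median_r, ctl$median_r)
  pn <- ec$per_network
  expect_gt(mean(pn$r[pn$group == "engineered"]),
            mean(pn$r[pn$group == "control"]))
})
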