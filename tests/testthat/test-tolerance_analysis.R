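test_that("a 1x1 phase diagram equals a single classification", {
  ctl <- sim_controls()
  pg <- phase_diagram(0.5, 1, ctl)
  oc <- classify_outcome(simulate_response(reduced_params(0.5, 1),
                                           controls = ctl), ctl)
  expect_equal(pg$labels[1, 1], oc$label)
  expect_equal(pg$peak_T[1, 1], oc$peak_T)
})

test_that("grid cells are independent: extending an axis preserves labels", {
  ctl <- sim_controls()
  small <- phase_diagram(c(0.3, 1.5), c(0.4, 1), ctl)
  bigger <- phase_diagram(c(0.3, 1.5, 2.5), c(0.4, 1), ctl)
  expect_identical(unname(small$labels), unname(bigger$labels[, 1:2]))
})

test_that("phase diagram axes are validated and rows concentrate tolerance at low alpha*", {
  expect_error(phase_diagram(c(1, 0.5), c(1, 2)), "increasing")
  expect_error(phase_diagram(numeric(0), 1), "non-empty")
  pg <- phase_diagram(c(0.1, 0.4, 1.2, 2.5), c(0.3, 2))
  # low-clearance row: tolerance then elimination along increasing alpha*
  expect_equal(unname(pg$labels[1, ]),
               c("TOLERANCE", "TOLERANCE", "TOLERANCE", "ELIMINATION"))
  # strong clearance eliminates everywhere
  expect_true(all(pg$labels[2, ] == "ELIMINATION"))
})

test_that("critical_alpha brackets, converges and post-verifies", {
  ca <- critical_alpha(list(beta_star = 1), c(0.5, 2), tol = 1e-3)
  expect_gt(as.numeric(ca), 0.5)
  expect_lt(as.numeric(ca), 2)
  # flanking classifications flip across the returned value
  lab <- function(a) classify_outcome(
    simulate_response(reduced_params(a, 1)))$label
  expect_equal(lab(as.numeric(ca) - 2e-3), "TOLERANCE")
  expect_equal(lab(as.numeric(ca) + 2e-3), "ELIMINATION")
  # halving the tolerance moves the estimate by at most the original tol
  ca2 <- critical_alpha(list(beta_star = 1), c(0.5, 2), tol = 5e-4)
  expect_lt(abs(as.numeric(ca2) - as.numeric(ca)), 1e-3)
})

test_that("critical_alpha rejects invalid brackets with informative labels", {
  expect_error(critical_alpha(list(beta_star = 1), c(2, 0.5)), "increasing")
  # swapped regimes: ELIMINATION at the low end
  expect_error(critical_alpha(list(beta_star = 1), c(1.5, 2)),
               "ELIMINATION")
  expect_error(critical_alpha(list(beta_star = 1), c(0.3, 0.6)),
               "TOLERANCE")
})

test_that("critical_alpha works in dimensional form and matches the reduced value", {
  # k = 1, lam = 1, P0 = 1 embeds the reduced system exactly
  ca_dim <- critical_alpha(list(k = 1, lam = 1, beta = 1), c(0.5, 2),
                           tol = 1e-4)
  ca_red <- critical_alpha(list(beta_star = 1), c(0.5, 2), tol = 1e-4)
  expect_lt(abs(as.numeric(ca_dim) - as.numeric(ca_red)), 2e-4)
})

test_that("threshold curve is non-increasing, deterministic, and marks undefined entries", {
  lams <- c(0.3, 0.6, 0.9)
  tc <- threshold_vs_affinity(lams, k = 1, beta = 1, P0 = 1,
                              bracket = c(0.01, 3), tol = 1e-3)
  expect_true(all(tc$defined))
  expect_true(all(diff(tc$critical_alpha) <= 0))
  tc2 <- threshold_vs_affinity(lams, k = 1, beta = 1, P0 = 1,
                               bracket = c(0.01, 3), tol = 1e-3)
  expect_identical(tc$critical_alpha, tc2$critical_alpha)
  # a very high affinity eliminates at every growth rate tried: undefined,
  # with no placeholder value
  tc3 <- threshold_vs_affinity(c(0.3, 5), k = 1, beta = 1, P0 = 1,
                               bracket = c(0.01, 3), tol = 1e-3)
  expect_false(tc3$defined[2])
  expect_true(is.na(tc3$critical_alpha[2]))
})

test_that("higher-affinity clones dominate the response", {
  cfg <- preset("three-clone")$config
  im <- immunodominance_experiment(cfg$clones, cfg$alpha,
                                   controls = cfg$controls)
  expect_equal(im$dominance_order, c("c1", "c2", "c3"))
  expect_true(all(diff(im$peaks$peak_T) < 0))
  expect_equal(im$outcome$label, "ELIMINATION")
  # two identical clones expand identically
  twin <- list(clone_params("a", 1, 1.5, 0.5), clone_params("b", 1, 1.5, 0.5))
  im2 <- immunodominance_experiment(twin, alpha = 1)
  expect_equal(im2$peaks$peak_T[1], im2$peaks$peak_T[2], tolerance = 1e-8)
  expect_error(immunodominance_experiment(twin[1], alpha = 1), "at least 2")
})

test_that("removing the dominant clone triggers compensatory expansion", {
  cfg <- preset("two-clone")$config
  cmp <- compensation_experiment(cfg$clones, "dominant", cfg$alpha,
                                 controls = cfg$controls)
  expect_gt(cmp$comparison$peak_depleted, cmp$comparison$peak_full)
  expect_equal(cmp$depleted$outcome$label, "ELIMINATION")
  # in the depleted run the survivor expands beyond its own two-clone peak
  expect_gt(cmp$comparison$ratio, 1)
  expect_error(
    compensation_experiment(cfg$clones, "nonexistent", cfg$alpha),
    "unknown clone")
  expect_error(
    compensation_experiment(cfg$clones[1], "dominant", cfg$alpha),
    "at least 2")
})

test_that("removing a negligible-affinity clone barely changes the others", {
  clones <- list(clone_params("main", k = 1, lam = 2, beta = 0.5),
                 clone_params("tiny", k = 1, lam = 0.01, beta = 0.01))
  cmp <- compensation_experiment(clones, "tiny", alpha = 2)
  expect_lt(abs(cmp$comparison$ratio - 1), 0.01)
})

test_that("the eliminated fast grower provokes the larger expansion", {
  cc <- preset("straddle")$config$compare
  res <- acute_vs_tolerated(list(beta_star = cc$beta_star), cc$alpha_lo,
                            cc$alpha_hi)
  expect_equal(res$tolerated$label, "TOLERANCE")
  expect_equal(res$acute$label, "ELIMINATION")
  expect_gt(res$peak_hi, res$peak_lo)
  expect_gt(res$peak_ratio, 1)
  expect_error(acute_vs_tolerated(list(beta_star = 1), 0.5, 0.5), "below")
  # swapped growth rates cannot straddle the threshold
  expect_error(acute_vs_tolerated(list(beta_star = 1), 2, 2.5), "straddle")
})
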