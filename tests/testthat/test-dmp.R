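test_that("M transformation is the clipped logit2", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(1), log2(0.999 / 0.001))
  expect_equal(beta_to_m(0), -log2(0.999 / 0.001))
  b <- matrix(c(0.2, 0.5, 0.9, 1), 2, 2)
  expect_equal(dim(beta_to_m(b)), dim(b))
})

test_that("constrained projection recovers pure and mixed compositions exactly", {
  ref <- make_test_reference(n_probes = 2000, seed = 31)
  pure <- simulate_samples(ref, 6, seed = 32, compositions = diag(6),
                           noise_precision = Inf)
  W <- estimate_cell_composition(pure$beta, ref)
  expect_equal(unname(W), diag(6), tolerance = 1e-6)

  half <- simulate_samples(ref, 1, seed = 33, noise_precision = Inf,
                           compositions = matrix(c(0.5, 0.5, 0, 0, 0, 0), 1))
  Wh <- estimate_cell_composition(half$beta, ref)
  expect_equal(unname(Wh)[1, ], c(0.5, 0.5, 0, 0, 0, 0), tolerance = 1e-6)

  expect_error(
    estimate_cell_composition(pure$beta[1:5, , drop = FALSE], ref),
    "marker")
})

test_that("constrained projection is accurate under beta noise", {
  ref <- make_test_reference(n_probes = 2000, seed = 34)
  mix <- simulate_samples(ref, 100, seed = 35, noise_precision = 100)
  W <- estimate_cell_composition(mix$beta, ref)
  expect_true(all(W >= 0))
  expect_true(all(rowSums(W) <= 1 + 1e-9))
  rmse <- sqrt(mean((W - mix$W)^2))
  expect_lt(rmse, 0.05)
})

test_that("per-probe least squares matches OLS identities", {
  set.seed(41)
  M <- matrix(rnorm(50 * 8), 50, 8)
  X <- matrix(1, 8, 1, dimnames = list(NULL, "intercept"))
  fit <- fit_probe_models(M, X)
  expect_equal(unname(fit$coefficients[, 1]), unname(rowMeans(M)))
  expect_equal(fit$s2, apply(M, 1, var))
  expect_equal(fit$df_residual, 7)

  # planted group difference with no noise is recovered exactly
  g <- rep(c(0, 1), each = 4)
  X2 <- cbind(intercept = 1, group = g)
  M2 <- matrix(rep(1:50, 8), 50, 8)
  M2[, g == 1] <- M2[, g == 1] + 0.7
  fit2 <- fit_probe_models(M2, X2)
  expect_equal(unname(fit2$coefficients[, "group"]), rep(0.7, 50))

  # collinear design rejected
  X3 <- cbind(intercept = 1, group = g, again = g)
  expect_error(fit_probe_models(M2, X3), "rank")
  expect_error(build_design(rep(c("case", "control"), 4),
                            composition = NULL), NA)
})

test_that("variance moderation recovers a planted prior and obeys its limits", {
  set.seed(7)
  ng <- 1e4; d0 <- 4; s02 <- 1; dg <- 10
  sigma2 <- d0 * s02 / rchisq(ng, d0)
  s2 <- sigma2 * rchisq(ng, dg) / dg
  eb <- ebayes_moderate(s2, dg)
  expect_lt(abs(eb$d0 - d0) / d0, 0.25)
  expect_lt(abs(eb$s02 - s02) / s02, 0.10)

  # all-equal variances: prior variance equals the common value and the
  # moderated statistic equals the ordinary t
  coef <- rnorm(200)
  ebc <- ebayes_moderate(rep(2.5, 200), 10, coef = coef, unscaled_var = 0.3)
  expect_equal(ebc$s02, 2.5)
  expect_equal(ebc$t, coef / sqrt(2.5 * 0.3))

  # d0 -> Inf: all posterior variances collapse to s0^2
  ebi <- ebayes_moderate(s2, dg, d0_override = Inf)
  expect_true(all(ebi$s2_post == ebi$s02))

  # d0 -> 0: moderated t tends to the ordinary t
  eb0 <- ebayes_moderate(s2[1:200], dg, coef = coef, unscaled_var = 0.3,
                         d0_override = 1e-9)
  expect_equal(eb0$t, coef / sqrt(s2[1:200] * 0.3), tolerance = 1e-6)

  expect_error(ebayes_moderate(c(s2[1:99], NA), dg), "non-finite|100")
})

test_that("variance moderation agrees with the reference empirical-Bayes fit", {
  set.seed(8)
  s2 <- 0.8 * rchisq(5000, 6) / 6 * (4 / rchisq(5000, 4))
  eb <- ebayes_moderate(s2, 6)
  fd <- limma::fitFDist(s2, df1 = 6)
  expect_equal(eb$d0, fd$df2, tolerance = 1e-6)
  expect_equal(eb$s02, fd$scale, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("dual-threshold probe selection applies both rules", {
  tab <- data.frame(probe_id = c("a", "b", "c"),
                    delta_beta = c(-0.15, -0.05, -0.30),
                    q = c(0.005, 0.005, 0.02),
                    direction = c("hypo", "hypo", "hypo"),
                    stringsAsFactors = FALSE)
  sel <- select_dmps(tab)
  expect_equal(sel$table$probe_id, "a")
  expect_equal(sel$n_hypo, 1)
  expect_equal(sel$n_hyper, 0)
})

test_that("cell-composition adjustment suppresses confounded probes", {
  ref <- make_test_reference(n_probes = 4000, seed = 51)
  # strong composition confounding, no planted probe effects
  co <- make_test_cohort(ref, seed = 52, n_probes = 4000L,
                         n_signature_probes = 0L, n_dmr_blocks = 0L,
                         n_controls = 40L,
                         dirichlet_cases = c(40, 4, 4, 4, 4, 4),
                         dirichlet_controls = c(4, 4, 4, 4, 4, 40))
  groups <- co$sheet$group
  adj <- select_dmps(dmp_analysis(co$beta, groups, reference = ref))
  unadj <- select_dmps(dmp_analysis(co$beta, groups))
  expect_gte(nrow(unadj$table), 10 * max(nrow(adj$table), 1))
})

test_that("dmp_analysis output table is coherent", {
  ref <- make_test_reference(n_probes = 3000, seed = 53)
  co <- make_test_cohort(ref, seed = 54, n_probes = 3000L,
                         n_signature_probes = 150L, n_dmr_blocks = 15L,
                         n_controls = 30L)
  dmp <- dmp_analysis(co$beta, co$sheet$group, reference = ref)
  tab <- dmp$table
  expect_true(all(tab$q >= 0 & tab$q <= 1))
  expect_true(all(tab$direction == ifelse(tab$delta_beta < 0, "hypo", "hyper")))
  expect_true(is.finite(dmp$model$d0) || dmp$model$d0 > 0)
  expect_error(dmp_analysis(co$beta, rep("control", ncol(co$beta))), "both")
})
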