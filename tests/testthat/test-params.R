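test_that("zi_params validates its domain", {
  p <- zi_params(10, 0.5, 0.6)
  expect_s3_class(p, "zi_params")
  expect_error(zi_params(0, 0.5, 0.6), "mu")
  expect_error(zi_params(10, -1, 0.6), "theta")
  expect_error(zi_params(10, 0.5, 1), "pi")
})

test_that("the scenario registry returns the factorial design tuples", {
  d1 <- scenario_effect("D1")
  expect_equal(c(d1$d_mu, d1$d_theta, d1$d_pi), c(0, 0, 0))
  d4 <- scenario_effect("D4")
  expect_equal(d4$d_pi, -1)
  d8 <- scenario_effect("D8")
  expect_equal(c(d8$d_mu, d8$d_theta, d8$d_pi), c(1, 0, 1))
  k3 <- scenario_effect("K3")
  expect_equal(c(k3$d_mu, k3$d_theta, k3$d_pi), c(1, 1, -1))
  expect_error(scenario_effect("D11"), "D1")
  expect_equal(nrow(scenario_effects()), 15)
})

test_that("effect application follows the half-per-side algebra", {
  base <- zi_params(10, 0.5, 0.6)
  # null effect is the identity
  same <- apply_effects(base, effect_vector(0, 0, 0), +1)
  expect_equal(unclass(same), unclass(base))
  # mu effect: exp(log 10 + 0.5)
  up <- apply_effects(base, effect_vector(1, 0, 0), +1)
  expect_equal(up$mu, exp(log(10) + 0.5))
  expect_equal(up$theta, 0.5)
  expect_equal(up$pi, 0.6)
  # pi effect on the logit scale: logistic(log(1.5) - 0.5)
  dn <- apply_effects(base, effect_vector(0, 0, -1), +1)
  expect_equal(dn$pi, plogis(log(0.6 / 0.4) - 0.5), tolerance = 1e-12)
  expect_equal(dn$pi, 0.4764, tolerance = 1e-4)
})

test_that("pi = 0 with a nonzero pi effect is rejected", {
  base <- zi_params(10, 0.5, 0)
  expect_error(apply_effects(base, effect_vector(0, 0, 1), +1), "logit")
  ok <- apply_effects(base, effect_vector(1, 0, 0), +1)
  expect_equal(ok$pi, 0)
})

test_that("effects are symmetric and group contrasts equal the effect exactly", {
  set.seed(42)
  for (i in 1:20) {
    base <- zi_params(exp(rnorm(1, 2)), exp(rnorm(1)), runif(1, 0.05, 0.95))
    eff <- effect_vector(rnorm(1), rnorm(1), rnorm(1))
    there <- apply_effects(base, eff, +1)
    back <- apply_effects(there, eff, -1)
    # two opposite half-steps return to baseline
    expect_equal(back$mu, base$mu, tolerance = 1e-12)
    expect_equal(back$theta, base$theta, tolerance = 1e-12)
    expect_equal(back$pi, base$pi, tolerance = 1e-12)
    # contrast between the two sides is the full effect
    lo <- apply_effects(base, eff, -1)
    expect_equal(log(there$mu) - log(lo$mu), eff$d_mu, tolerance = 1e-12)
    expect_equal(log(there$theta) - log(lo$theta), eff$d_theta, tolerance = 1e-12)
    expect_equal(qlogis(there$pi) - qlogis(lo$pi), eff$d_pi, tolerance = 1e-9)
  }
})

test_that("subgroup parameters compose disease then batch effects", {
  base <- zi_params(10, 0.5, 0.6)
  all_null <- subgroup_params(base, scenario_effect("D1"), scenario_effect("K1"))
  for (s in all_null) expect_equal(unclass(s), unclass(base))
  # no batch effect: batches identical within disease group
  d2 <- subgroup_params(base, scenario_effect("D2"), scenario_effect("K1"))
  expect_equal(unclass(d2$D1), unclass(d2$D2))
  expect_equal(unclass(d2$H1), unclass(d2$H2))
  # K3: between-batch log-mu contrast within a disease group is kappa_mu = 1
  k3 <- subgroup_params(base, scenario_effect("D1"), scenario_effect("K3"))
  expect_equal(log(k3$D1$mu) - log(k3$D2$mu), 1, tolerance = 1e-12)
  expect_equal(log(k3$H1$mu) - log(k3$H2$mu), 1, tolerance = 1e-12)
  # the double_batch reading doubles the contrast
  k3d <- subgroup_params(base, scenario_effect("D1"), scenario_effect("K3"),
                         double_batch = TRUE)
  expect_equal(log(k3d$D1$mu) - log(k3d$D2$mu), 2, tolerance = 1e-12)
})

test_that("effect_vector refuses a mismatched registry label", {
  expect_error(effect_vector(2, 0, 0, label = "D2"), "registry")
  expect_silent(effect_vector(1, 0, 0, label = "D2"))
})
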