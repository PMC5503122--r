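test_that("objective matches per-site re-summation", {
  p <- fe3_truth()
  # zero at the generating parameters, no noise
  pop <- generate_population(synthetic_config(
    p, n_sites = 30, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0, seed = 31))
  expect_equal(bv_objective(p, pop$sites), 0, tolerance = 1e-20)
  # one homoleptic site with V = S + 1 contributes exactly 1
  s <- fe_site(rep(typical_distance(1.70, 3, 6), 6), ligand = "N",
               oxidation = 2)  # true sum 3, expected 2
  pN <- make_params("Fe2-N" = 1.70)
  expect_equal(bv_objective(pN, list(s)), 1, tolerance = 1e-12)
  # three toy sites: brute-force re-summation oracle
  toys <- list(
    binding_site("Fe", c("N", "N", "O"), c(2.0, 2.1, 2.2), oxidation = 3),
    binding_site("Fe", rep("O", 4), c(1.9, 2.0, 2.05, 2.3), oxidation = 3),
    binding_site("Fe", c("N", "O"), c(1.95, 2.25), oxidation = 3)
  )
  oracle <- sum(vapply(toys, function(st) (bvs(st, p) - 3)^2, 0))
  expect_equal(bv_objective(p, toys), oracle, tolerance = 1e-12)
})

test_that("analytic gradient agrees with central finite differences", {
  p <- fe3_truth()
  set.seed(33)
  pop <- generate_population(synthetic_config(
    p, n_sites = 40, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0.05, seed = 33))
  g <- bv_gradient(p, pop$sites)
  h <- 1e-6
  for (key in names(g)) {
    up <- set_param(p, key, get_r0(p, key) + h)
    dn <- set_param(p, key, get_r0(p, key) - h)
    fd <- (bv_objective(up, pop$sites) - bv_objective(dn, pop$sites)) / (2 * h)
    expect_equal(g[[key]], fd, tolerance = 1e-5)
  }
  # zero-residual population has an all-zero gradient
  clean <- generate_population(synthetic_config(
    p, n_sites = 25, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0, seed = 34))
  expect_true(all(abs(bv_gradient(p, clean$sites)) < 1e-10))
})

test_that("noise-free parameter recovery is exact for all population shapes", {
  shapes <- list(
    homoleptic = list(hf = 0, pool = c(N = 1)),
    heteroleptic = list(hf = 1, pool = c(N = 1, O = 1)),
    mixed = list(hf = 0.5, pool = c(N = 1, O = 1))
  )
  for (shape in shapes) {
    tp <- fe3_truth()
    pop <- generate_population(synthetic_config(
      tp, n_sites = 200, metal = "Fe", oxidation = 3,
      heteroleptic_fraction = shape$hf, ligand_pool = shape$pool,
      distance_noise_sd = 0, seed = 35))
    fit <- fit_r0(pop$sites, fe3_literature_init())
    for (key in fit$fitted_keys) {
      expect_lt(abs(get_r0(fit$params, key) - get_r0(tp, key)), 1e-6)
    }
    expect_true(fit$converged)
  }
})

test_that("noise-free homoleptic fit equals the closed-form solution", {
  tp <- make_params("Fe2-N" = 1.76)
  pop <- generate_population(synthetic_config(
    tp, n_sites = 50, metal = "Fe", oxidation = 2,
    heteroleptic_fraction = 0, ligand_pool = c(N = 1),
    distance_noise_sd = 0, seed = 36))
  fit <- fit_r0(pop$sites, make_params("Fe2-N" = 1.86))
  # every site's closed-form R0 equals the fitted value
  per_site <- vapply(pop$sites, homoleptic_r0, 0)
  expect_equal(max(abs(per_site - get_r0(fit$params, "Fe2-N"))), 0,
               tolerance = 1e-6)
})

test_that("objective trace is monotone non-increasing over accepted steps", {
  tp <- fe3_truth()
  pop <- generate_population(synthetic_config(
    tp, n_sites = 120, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0.03, seed = 37))
  fit <- fit_r0(pop$sites, fe3_literature_init())
  expect_true(all(diff(fit$objective_trace) <=
                    1e-12 * pmax(1, fit$objective_trace[-1])))
})

test_that("window pruning removes planted outliers without moving the fit", {
  tp <- fe3_truth()
  mk <- function(outliers) generate_population(synthetic_config(
    tp, n_sites = 200, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0, outlier_fraction = outliers, seed = 38))
  clean <- mk(0)
  pois <- mk(0.05)
  expect_gt(sum(pois$truth$outlier), 0)
  # planted sites exceed the window under the true parameters
  bad_ids <- pois$truth$site_id[pois$truth$outlier]
  v_bad <- vapply(pois$sites[match(bad_ids, pois$truth$site_id)],
                  bvs, 0, params = tp)
  expect_true(all(v_bad > 2 * 3))
  fit_c <- fit_r0(clean$sites, fe3_literature_init())
  fit_p <- fit_r0(pois$sites, fe3_literature_init())
  expect_setequal(fit_p$pruned_sites$site_id, bad_ids)
  for (key in fit_p$fitted_keys) {
    expect_lt(abs(get_r0(fit_p$params, key) - get_r0(fit_c$params, key)),
              1e-6)
  }
  # pruning is stable: refitting the kept set reproduces the parameters
  fit_again <- fit_r0(fit_p$sites, fit_p$params)
  for (key in fit_p$fitted_keys) {
    expect_lt(abs(get_r0(fit_again$params, key) - get_r0(fit_p$params, key)),
              1e-10)
  }
  expect_equal(nrow(fit_again$pruned_sites), 0L)
})

test_that("uncertainty matches the closed form and bounds the R0 spread", {
  tp <- make_params("Fe3-N" = 1.70)
  pop <- generate_population(synthetic_config(
    tp, n_sites = 150, metal = "Fe", oxidation = 3,
    heteroleptic_fraction = 0, ligand_pool = c(N = 1),
    distance_noise_sd = 0.02, seed = 39))
  fit <- fit_r0(pop$sites, make_params("Fe3-N" = 1.86))
  unc <- fit$uncertainty[["Fe3-N"]]
  # homoleptic-only: equals sqrt(mean (b ln(S/V_i))^2) directly
  V <- vapply(fit$sites, bvs, 0, params = fit$params)
  S <- vapply(fit$sites, function(s) s$oxidation, 0L)
  expect_equal(unc, sqrt(mean((0.37 * log(S / V))^2)), tolerance = 1e-10)
  # bound: never below the population sd of per-site closed-form R0
  per_site <- vapply(fit$sites, homoleptic_r0, 0)
  pop_sd <- sqrt(mean((per_site - mean(per_site))^2))
  expect_gte(unc, pop_sd - 1e-12)
  # zero-residual population: uncertainty 0 for every type
  clean <- generate_population(synthetic_config(
    fe3_truth(), n_sites = 40, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0, seed = 40))
  u0 <- bv_uncertainty(clean$sites, fe3_truth())
  expect_true(all(u0 < 1e-10))
})

test_that("noisy recovery has small bias and a calibrated uncertainty", {
  tp <- fe3_truth()
  pop <- generate_population(synthetic_config(
    tp, n_sites = 500, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0.02, seed = 41))
  fit <- fit_r0(pop$sites, fe3_literature_init())
  for (key in fit$fitted_keys) {
    expect_lt(abs(get_r0(fit$params, key) - get_r0(tp, key)), 0.01)
  }
  # reported uncertainty bounds the spread of per-site homoleptic re-estimates
  homo <- Filter(is_homoleptic, fit$sites)
  keys <- vapply(homo, function(s) bond_type_key("Fe", 3, s$contacts$ligand[1]), "")
  for (key in unique(keys)) {
    r0s <- vapply(homo[keys == key], homoleptic_r0, 0)
    pop_sd <- sqrt(mean((r0s - mean(r0s))^2))
    expect_gte(fit$uncertainty[[key]], pop_sd - 1e-12)
  }
})

test_that("homoleptic_summary follows its conventions", {
  s1 <- fe_site(rep(2.0, 6), oxidation = 2, id = "a")
  expect_equal(homoleptic_summary(list(s1))$mean_r0, homoleptic_r0(s1))
  expect_equal(homoleptic_summary(list(s1))$sd_r0, 0)
  # two sites at r +/- delta: mean r, sample sd sqrt(2) * delta
  r0a <- 1.75; delta <- 0.01
  mk <- function(r0, id) fe_site(rep(typical_distance(r0, 2, 6), 6), id = id)
  sm <- homoleptic_summary(list(mk(r0a - delta, "a"), mk(r0a + delta, "b")))
  expect_equal(sm$mean_r0, r0a, tolerance = 1e-12)
  expect_equal(sm$sd_r0, sqrt(2) * delta, tolerance = 1e-12)
  expect_equal(sm$n, 2L)
  # heteroleptic sites are excluded; empty types omitted
  het <- binding_site("Fe", c("N", "O"), c(2, 2.1), oxidation = 2)
  expect_equal(nrow(homoleptic_summary(list(het))), 0L)
  # synthetic population: mean within noise tolerance of the truth
  tp <- make_params("Fe2-N" = 1.76)
  pop <- generate_population(synthetic_config(
    tp, n_sites = 120, metal = "Fe", oxidation = 2,
    heteroleptic_fraction = 0, ligand_pool = c(N = 1),
    distance_noise_sd = 0.02, seed = 43))
  sm2 <- homoleptic_summary(pop$sites)
  expect_lt(abs(sm2$mean_r0 - 1.76), 0.01)
})

test_that("fit_r0 validates inputs and reports failure states", {
  tp <- fe3_truth()
  pop <- generate_population(synthetic_config(
    tp, n_sites = 10, metal = "Fe", oxidation = 3,
    distance_noise_sd = 0, seed = 44))
  mixed <- pop$sites
  mixed[[1]]$oxidation <- 2L
  expect_error(fit_r0(mixed, fe3_literature_init()), "single metal species")
  # a site whose bond type is absent from the initial parameters
  expect_error(fit_r0(pop$sites, make_params("Fe3-N" = 1.86)),
               "missing-parameter")
  expect_error(fit_r0(pop$sites, fe3_literature_init(),
                      fit_config(max_iterations = 1,
                                 gradient_tolerance = 1e-14)),
               "did not converge")
})
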