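test_that("initialize_from_kratky inverts peak positions into size seeds", {
  # single component: seed rg within 15% of truth
  g <- ggp_params(1, 1.6, 4, 0)
  p1 <- simulate_profile(composite_model(ggp = list(g)), noise = NULL)
  init1 <- initialize_from_kratky(p1, 1)
  expect_equal(length(init1$ggp), 1)
  expect_lt(abs(init1$ggp[[1]]$rg - 1.6) / 1.6, 0.15)

  # 60 mol % composite: two seeds near sqrt(3)/0.3 and sqrt(3)/1.1
  p2 <- simulate_profile(model60(), noise = NULL)
  init2 <- initialize_from_kratky(p2, 2)
  expect_equal(length(init2$ggp), 2)
  rgs <- sort(vapply(init2$ggp, `[[`, numeric(1), "rg"), decreasing = TRUE)
  expect_lt(abs(rgs[1] - sqrt(3) / 0.3) / (sqrt(3) / 0.3), 0.2)
  expect_lt(abs(rgs[2] - sqrt(3) / 1.1) / (sqrt(3) / 1.1), 0.2)

  # flat profile: no components, flat background fallback, with a notice
  flat <- saxs_profile(make_q_grid(), rep(2, 256))
  expect_message(init3 <- initialize_from_kratky(flat, 2), "peak")
  expect_equal(length(init3$ggp), 0)
  expect_equal(init3$background, 2)
})

test_that("noise-free composite fits recover generating parameters exactly", {
  m <- model60()
  prof <- simulate_profile(m, noise = NULL)
  fit <- fit_composite(prof, initialize_from_kratky(prof, 2), multistart = 2)
  expect_true(fit$converged)
  truth <- c(ggp1.i0 = 1, ggp1.rg = 5.9, ggp1.d = 4, ggp1.s = 0,
             ggp2.i0 = 0.5, ggp2.rg = 1.6, ggp2.d = 4, ggp2.s = 0.1,
             porod.D = m$porod$prefactor, porod.d = 4)
  expect_equal(fit$par[names(truth)], truth, tolerance = 1e-7)
  expect_lt(fit$chi2_reduced, 1e-16)
  expect_equal(length(fit$residuals), length(prof$q))
  expect_true(all(fit$stderr[is.finite(fit$stderr)] >= 0))
})

test_that("fitting initialized at truth is a fixed point on noise-free data", {
  for (conc in c(30, 60, 80)) {
    m <- reference_model(conc)
    prof <- simulate_profile(m, noise = NULL)
    fit <- fit_composite(prof, m, multistart = 1)
    rg1_true <- reference_series_params()$rg1[
      reference_series_params()$concentration == conc]
    expect_equal(fit$par[["ggp1.rg"]], rg1_true, tolerance = 1e-9)
    expect_lt(fit$chi2_reduced, 1e-16)
  }
})

test_that("noisy composite fits recover rg within 3 reported stderr", {
  m <- model60()
  p <- simulate_profile(m, noise = noise_model(level = 0.02, seed = 11))
  fit <- fit_composite(p, initialize_from_kratky(p, 2))
  expect_lt(abs(fit$par[["ggp1.rg"]] - 5.9), 3 * fit$stderr[["ggp1.rg"]])
  expect_lt(abs(fit$par[["ggp2.rg"]] - 1.6), 3 * fit$stderr[["ggp2.rg"]])
})

test_that("fixed-parameter masks hold values and drop stderr entries", {
  g <- ggp_params(1, 1.6, 4, 0)
  prof <- simulate_profile(composite_model(ggp = list(g)),
                           noise = noise_model(level = 0.02, seed = 3))
  fit <- fit_composite(prof, composite_model(ggp = list(g)),
                       fixed = c("ggp1.rg", "ggp1.s"), multistart = 1)
  expect_equal(fit$par[["ggp1.rg"]], 1.6)
  expect_equal(fit$par[["ggp1.s"]], 0)
  expect_true(is.na(fit$stderr[["ggp1.rg"]]))
  expect_true(is.na(fit$stderr[["ggp1.s"]]))
  expect_equal(fit$n_free, 2)
})

test_that("label-swap symmetry: permuted init gives the same curve, rg-ordered report", {
  m <- model60()
  prof <- simulate_profile(m, noise = NULL)
  init <- initialize_from_kratky(prof, 2)
  init_swapped <- composite_model(ggp = rev(init$ggp), porod = init$porod)
  f1 <- fit_composite(prof, init, multistart = 1)
  f2 <- fit_composite(prof, init_swapped, multistart = 1)
  expect_equal(f2$residuals, f1$residuals, tolerance = 1e-6)
  expect_gt(f1$model$ggp[[1]]$rg, f1$model$ggp[[2]]$rg)
  expect_gt(f2$model$ggp[[1]]$rg, f2$model$ggp[[2]]$rg)
  # a noisy fit still reports components in descending-rg order
  pn <- simulate_profile(m, noise = noise_model(level = 0.02, seed = 5))
  fn <- fit_composite(pn, initialize_from_kratky(pn, 2), multistart = 1)
  expect_gt(fn$model$ggp[[1]]$rg, fn$model$ggp[[2]]$rg)
})

test_that("parameter recovery is calibrated: mean deviation below mean stderr", {
  g <- ggp_params(1, 1.6, 4, 0)
  m <- composite_model(ggp = list(g))
  devs <- ses <- numeric(0)
  for (s in 1:20) {
    p <- simulate_profile(m, noise = noise_model(level = 0.02, seed = 200 + s))
    f <- fit_composite(p, m, multistart = 1)
    devs <- c(devs, f$par[["ggp1.rg"]] - 1.6)
    ses <- c(ses, f$stderr[["ggp1.rg"]])
  }
  expect_lt(abs(mean(devs)), mean(ses))
})

test_that("reported stderr scales roughly as 1/sqrt(n)", {
  db <- db_params(100, 4.8)
  se_at_n <- function(n) {
    cfg <- instrument_config(n_points = n)
    p <- simulate_profile(db, cfg, noise_model(level = 0.02, seed = 9))
    fit_debye_bueche(p)$stderr[["xi"]]
  }
  ratio <- se_at_n(64) / se_at_n(256)
  expect_gt(ratio, 1)       # fewer points, larger uncertainty
  expect_lt(ratio, 4)       # within a factor of 2 of the ideal sqrt(4) = 2
})

test_that("debye-bueche fits: inverse crime and linearized consistency", {
  db <- db_params(100, 4.8)
  p <- simulate_profile(db, noise = NULL)
  fit <- fit_debye_bueche(p)
  expect_equal(fit$par[["xi"]], 4.8, tolerance = 1e-7)
  expect_equal(fit$par[["A"]], 100, tolerance = 1e-7)
  # linearized diagnostic agrees with the nonlinear fit within 1%
  expect_lt(abs(fit$linearized$xi - fit$par[["xi"]]) / fit$par[["xi"]], 0.01)
  expect_error(fit_debye_bueche(restrict_q(p, 0.142, 0.16)), "insufficient")
})

test_that("db+oz nested-model behaviour and model comparison", {
  db <- db_params(100, 4.8)
  p_db <- simulate_profile(db, noise = noise_model(level = 0.02, seed = 21))
  f_db <- fit_debye_bueche(p_db)
  f_both <- fit_db_plus_oz(p_db)
  # OZ amplitude consistent with zero: negligible against the DB amplitude
  a_oz <- f_both$par[["A_oz"]]
  se_oz <- f_both$stderr[["A_oz"]]
  expect_true((is.finite(se_oz) && a_oz < 2 * se_oz) ||
                a_oz < 1e-3 * f_both$par[["A_db"]])
  cmp <- compare_models(list(f_db, f_both))
  expect_equal(cmp$best$kind, "debye_bueche")
  expect_false(cmp$ranking$required[cmp$ranking$kind == "db_plus_oz"])

  # a genuine DB+OZ mixture: both correlation lengths recovered
  mix_q <- make_q_grid()
  mu <- debye_bueche_intensity(db, mix_q) +
    ornstein_zernike_intensity(oz_params(30, 1.2), mix_q)
  pm <- saxs_profile(mix_q, mu)
  f_mix <- fit_db_plus_oz(pm)
  expect_equal(f_mix$par[["xi_db"]], 4.8, tolerance = 1e-4)
  expect_equal(f_mix$par[["xi_oz"]], 1.2, tolerance = 1e-4)

  # singleton comparison returns the fit itself
  single <- compare_models(list(f_db))
  expect_equal(single$selected, 1)
  expect_error(compare_models(list(f_db, fit_debye_bueche(p_db, window = c(0.2, 2)))),
               "different")
})
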