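test_that("ggp_crossover and ggp_porod_prefactor match hand-evaluated values", {
  p <- ggp_params(i0 = 1, rg = 1.6, d = 4, s = 0)
  expect_equal(ggp_crossover(p), sqrt(6) / 1.6, tolerance = 1e-12)
  expect_equal(ggp_porod_prefactor(p), (sqrt(6) / 1.6)^4 * exp(-2),
               tolerance = 1e-12)
  p2 <- ggp_params(i0 = 2, rg = 3, d = 3, s = 0)
  expect_equal(ggp_crossover(p2), (3 / sqrt(2)) / 3, tolerance = 1e-12)
  # d -> s+ sends the crossover to zero
  p3 <- ggp_params(i0 = 1, rg = 2, d = 1e-6, s = 0)
  expect_lt(ggp_crossover(p3), 1e-3)
  expect_error(ggp_params(1, 1.6, d = 2, s = 2.5), "exceed")
  expect_error(ggp_params(1, 1.6, d = 4, s = 3), "s")
})

test_that("ggp_intensity matches the closed form on both branches", {
  p <- ggp_params(i0 = 1, rg = 1.6, d = 4, s = 0)
  # Guinier branch hand evaluation at q = 0.5
  expect_equal(ggp_intensity(p, 0.5), exp(-0.25 * 2.56 / 3), tolerance = 1e-12)
  # Guinier limit: I -> i0 as q -> 0 for s = 0
  expect_equal(ggp_intensity(p, 1e-6), 1, tolerance = 1e-9)
  # power-law scaling on the Porod branch
  q1 <- ggp_crossover(p)
  expect_equal(ggp_intensity(p, 2 * q1), ggp_intensity(p, q1) / 2^4,
               tolerance = 1e-12)
})

test_that("GGP branches join with value and slope continuity (property)", {
  for (p in random_ggp(25)) {
    q1 <- ggp_crossover(p)
    guinier <- p$i0 * q1^(-p$s) * exp(-q1^2 * p$rg^2 / (3 - p$s))
    porod <- ggp_porod_prefactor(p) * q1^(-p$d)
    expect_lt(abs(guinier - porod) / guinier, 1e-12)
    # log-log slope approaching q1 from the Guinier side equals -d
    h <- 5e-8
    qa <- q1 * (1 - 2 * h)        # both points still on the Guinier branch
    slope <- (log(ggp_intensity(p, q1)) - log(ggp_intensity(p, qa))) /
      (log(q1) - log(qa))
    expect_lt(abs(slope + p$d), 1e-6)
  }
})

test_that("GGP is monotone decreasing for s = 0 and obeys the Guinier expansion", {
  p <- ggp_params(i0 = 2, rg = 3.2, d = 4, s = 0)
  q <- seq(0.01, 5, length.out = 400)
  expect_true(all(diff(ggp_intensity(p, q)) < 0))
  # I/i0 - (1 - q^2 rg^2/3) vanishes like q^4 near zero
  err <- function(q) abs(ggp_intensity(p, q) / p$i0 - (1 - q^2 * p$rg^2 / 3))
  expect_lt(err(1e-3), 1e-9)
  expect_gt(err(2e-3) / err(1e-3), 10)  # ~16 for a q^4 remainder
})

test_that("porod, debye-bueche and ornstein-zernike curves follow their laws", {
  po <- porod_params(1, 4)
  expect_equal(porod_intensity(po, c(1, 2)), c(1, 1 / 16))
  qs <- c(0.3, 0.9, 2.7)
  logslope <- diff(log(porod_intensity(po, qs))) / diff(log(qs))
  expect_equal(logslope, c(-4, -4), tolerance = 1e-12)

  db <- db_params(100, 4.8)
  expect_equal(debye_bueche_intensity(db, 0), 100)
  expect_equal(debye_bueche_intensity(db, 1 / 4.8), 25)
  # I^(-1/2) is linear in q^2 with slope xi^2/sqrt(A), intercept 1/sqrt(A)
  q <- seq(0.1, 2, length.out = 50)
  y <- debye_bueche_intensity(db, q)^(-0.5)
  co <- coef(lm(y ~ I(q^2)))
  expect_equal(unname(co[1]), 1 / 10, tolerance = 1e-10)
  expect_equal(unname(co[2]), 4.8^2 / 10, tolerance = 1e-10)

  oz <- oz_params(50, 2)
  expect_equal(ornstein_zernike_intensity(oz, 0), 50)
  expect_equal(ornstein_zernike_intensity(oz, 0.5), 25)
  yi <- 1 / ornstein_zernike_intensity(oz, q)
  co2 <- coef(lm(yi ~ I(q^2)))
  expect_equal(unname(co2[2]) / unname(co2[1]), 4, tolerance = 1e-10)
})

test_that("composite_intensity is the sum of its parts", {
  g1 <- ggp_params(1, 5.9, 4, 0)
  g2 <- ggp_params(0.5, 1.6, 4, 0.1)
  po <- porod_params(1e-4, 4)
  q <- make_q_grid()
  single <- composite_model(ggp = list(g1))
  expect_equal(composite_intensity(single, q), ggp_intensity(g1, q))
  both <- composite_model(ggp = list(g1, g2), porod = po, background = 0.01)
  expect_equal(composite_intensity(both, q),
               ggp_intensity(g1, q) + ggp_intensity(g2, q) +
                 porod_intensity(po, q) + 0.01)
  expect_error(composite_model(), "at least one")
})

test_that("globular components at Rg 5.9 and 1.6 peak near 0.3 and 1.1 nm^-1", {
  # Kratky peak positions are amplitude-invariant; the published readings
  # assume globular scatterers (s = 0)
  large <- ggp_params(1, 5.9, 4, 0)
  small <- ggp_params(1, 1.6, 4, 0)
  expect_equal(round(kratky_peak_q(large), 1), 0.3)
  expect_equal(round(kratky_peak_q(small), 1), 1.1)
  expect_equal(kratky_peak_q(small), sqrt(3) / 1.6, tolerance = 1e-12)
})

test_that("sphere_diameter applies the uniform-sphere relation and round-trips", {
  expect_equal(sphere_diameter(0), 0)
  expect_equal(sphere_diameter(1.6), 2 * sqrt(5 / 3) * 1.6)
  expect_error(sphere_diameter(-1), "nonnegative")
  # round trip: rg(R) * sqrt(5/3) = R
  rg <- c(1.6, 4.7, 7.9)
  R <- sphere_diameter(rg) / 2
  expect_equal(R / sqrt(5 / 3), rg, tolerance = 1e-12)
})

test_that("kratky_peak_q closed form agrees with a brute-force grid argmax", {
  # a Kratky peak exists in the Guinier branch only for s < 2 and d > 2
  draws <- Filter(function(p) p$s < 2 && p$d > 2.1, random_ggp(15, seed = 7))
  for (p in draws) {
    q_star <- kratky_peak_q(p)
    qs <- exp(seq(log(1e-3), log(1e2), length.out = 1e5))
    k <- qs^2 * ggp_intensity(p, qs)
    i <- which.max(k)
    step <- qs[i + 1] - qs[i - 1]
    expect_lt(abs(q_star - qs[i]), step)
  }
  expect_error(kratky_peak_q(ggp_params(1, 2, d = 2.5, s = 2.2)), "s >= 2")
})

test_that("model config serialization round-trips", {
  m <- composite_model(ggp = list(ggp_params(1, 5.9, 4, 0),
                                  ggp_params(0.5, 1.6, 4, 0.1)),
                       porod = porod_params(1e-4, 4), background = 0.02)
  m2 <- model_from_config(model_to_config(m))
  expect_equal(m2, m)
  db <- db_params(100, 4.8)
  expect_equal(model_from_config(model_to_config(db)), db)
})
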