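test_that("strain demands follow the principal-strain definition", {
  d <- demand(c(0.004, 0.001, -0.002))
  expect_equal(d$tension, 0.004)
  expect_equal(d$compression, 0.002)
  d0 <- demand(c(0, 0, 0))
  expect_equal(d0$tension, 0)
  expect_equal(d0$compression, 0)
  ## uniaxial compression, lateral free: principal strains (nu e, nu e, -e)
  du <- demand(c(0.003, 0.003, -0.010))
  expect_equal(du$tension, 0.003)
  expect_equal(du$compression, 0.010)
})

test_that("material_params rejects inconsistent thresholds", {
  expect_error(material_params(12000, 0.3, 0.0061, 0.0033, 0.0081, 0.0102))
  expect_error(material_params(12000, 0.3, 0.0033, 0.0061, 0.0081, 0.0102,
                               postyield_ratio = 1.2))
  expect_error(material_params(-1, 0.3, 0.0033, 0.0061, 0.0081, 0.0102))
  expect_error(material_params(12000, 0.3, 0.0033, 0.0061, 0.0081, 0.0102,
                               G_f = 0))
})

test_that("single-element uniaxial curves are bilinear with exact knees", {
  m <- trab()
  for (mode in c("tension", "compression")) {
    ey <- if (mode == "tension") m$eps_yield_t else m$eps_yield_c
    ec <- if (mode == "tension") m$eps_crack_t else m$eps_crack_c
    res <- uniaxial_ramp(mode, to = ec - 1e-4)
    s <- res$steps
    el <- s$strain <= ey + 1e-12
    expect_lt(max(abs(s$stress[el] - m$E * s$strain[el])), 1e-6 * m$E * ey)
    pl <- s$strain > ey + 1e-12
    sig_expect <- m$E * (ey + m$postyield_ratio * (s$strain[pl] - ey))
    expect_lt(max(abs(s$stress[pl] - sig_expect) / sig_expect), 1e-9)
  }
})

test_that("crack initiation flags flip just past the crack strains", {
  m <- trab()
  rt <- uniaxial_ramp("tension", to = 0.0070)
  s <- rt$steps
  first <- s$strain[which(s$n_cracked > 0)[1]]
  expect_lt(abs(first - m$eps_crack_t), 5.01e-5)
  rc <- uniaxial_ramp("compression", to = 0.0110)
  sc <- rc$steps
  firstc <- sc$strain[which(sc$n_cracked > 0)[1]]
  expect_lt(abs(firstc - m$eps_crack_c), 5.01e-5)
})

test_that("crack-band span follows the energy closed form", {
  m <- trab()
  ## sigma0 from the bilinear curve at the tensile crack strain
  sigma0 <- m$E * (m$eps_yield_t + m$postyield_ratio *
                     (m$eps_crack_t - m$eps_yield_t))
  expect_equal(sigma0, 41.28)
  expect_equal(dissipate_Gf(m, 0.035), 2 * 0.33 / (41.28 * 0.035),
               tolerance = 1e-12)
  expect_equal(dissipate_Gf(m, 0.035), 0.457, tolerance = 1e-3)
  ## doubling the element halves the span
  expect_equal(dissipate_Gf(m, 0.070), dissipate_Gf(m, 0.035) / 2)
  ## vanishing fracture energy: instant failure
  m2 <- material_preset("trabecular", G_f = 1e-9)
  expect_lt(dissipate_Gf(m2, 0.035), 1e-6)
  expect_error(dissipate_Gf(m, 0), "positive")
  expect_error(dissipate_Gf(m, 0.035, init_stress = -1), "positive")
})

test_that("damage never heals under arbitrary demand histories", {
  m <- trab()
  set.seed(42)
  st <- damage_state(50)
  prev_scale <- st$scale
  prev_d <- st$d
  for (k in 1:30) {
    dem <- list(tension = runif(50, 0, 0.02), compression = runif(50, 0, 0.03))
    st <- update_state(st, dem, m, 0.035)
    expect_true(all(st$scale <= prev_scale + 1e-15))
    expect_true(all(st$d >= prev_d - 1e-15))
    prev_scale <- st$scale
    prev_d <- st$d
  }
  expect_true(all(st$d >= 0 & st$d <= 1))
  expect_true(all(st$cracked[st$d > 0]))
})

test_that("the larger demand ratio governs, with ties going to tension", {
  ## power-of-two thresholds so the demand ratios tie exactly in floating point
  m <- material_params(E = 1000, nu = 0.3,
                       eps_yield_t = 0.25, eps_crack_t = 0.5,
                       eps_yield_c = 0.5, eps_crack_c = 2)
  h <- 0.035
  ## exact tie at ratio 9/4: tension just past crack, compression post-yield;
  ## the tension softening branch must govern
  st <- update_state(damage_state(1),
                     list(tension = 0.5625, compression = 1.125), m, h)
  span_t <- dissipate_Gf(m, h, mode = "tension")
  sig0_t <- m$eps_yield_t + m$postyield_ratio * (m$eps_crack_t - m$eps_yield_t)
  s_expect <- sig0_t * (1 - (0.5625 - m$eps_crack_t) / span_t) / 0.5625
  expect_equal(st$scale, s_expect, tolerance = 1e-12)
  expect_true(st$cracked)
  ## strictly larger compression ratio governs compression
  st2 <- update_state(damage_state(1), list(tension = 0.3, compression = 1.5),
                      m, h)
  s_c <- (m$eps_yield_c + m$postyield_ratio * (1.5 - m$eps_yield_c)) / 1.5
  expect_equal(st2$scale, s_c, tolerance = 1e-12)
})

test_that("band dissipation equals G_f times crack area across mesh sizes", {
  m <- trab()
  for (h_um in c(17.5, 35, 70)) {
    bd <- band_dissipation(h_um)
    expected <- bd$weak * m$G_f * bd$area
    expect_lt(abs(bd$dissipated - expected) / expected, 0.05)
  }
})
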