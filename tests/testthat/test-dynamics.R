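test_that("kappa-rule and conservation identities hold at arbitrary states", {
  p <- reference_params()
  # generalized-animal state at L = 0.5, e = 1, adult
  E_m <- p$p_Am / p$v
  pw <- deb_powers(p, E = E_m * 0.5^3, L = 0.5, E_H = p$E_Hp)
  # each flux recomputed independently from its formula
  p_A <- p$p_Am * 0.5^2
  p_S <- p$p_M * 0.5^3
  p_C <- (E_m * 0.5^3) * (p$E_G * p$v * 0.5^2 + p_S) /
    (p$kap * E_m * 0.5^3 + p$E_G * 0.5^3)
  expect_equal(pw$p_A, p_A)
  expect_equal(pw$p_S, p_S)
  expect_equal(pw$p_C, p_C)
  expect_lt(abs(pw$p_C - pw$p_S - pw$p_G - pw$p_J - pw$p_R) / pw$p_C, 1e-12)
  expect_lt(abs(p$kap * pw$p_C - pw$p_S - pw$p_G) / pw$p_C, 1e-12)
  expect_lt(abs((1 - p$kap) * pw$p_C - pw$p_J - pw$p_R) / pw$p_C, 1e-12)
  # and along a whole trajectory
  st <- ref_traj()$states
  rel <- abs(st$p_C - st$p_S - st$p_G - st$p_J - st$p_R) / pmax(st$p_C, 1e-300)
  expect_lt(max(rel), 1e-10)
})

test_that("growth ceases at ultimate size and embryos do not feed", {
  p <- reference_params()
  E_m <- p$p_Am / p$v
  pw <- deb_powers(p, E = E_m, L = 1, E_H = p$E_Hp)  # e = f = 1, L = L_m
  expect_equal(pw$p_G, 0, tolerance = 1e-12)
  pw_e <- deb_powers(p, E = 1, L = 0.03, E_H = 0.1)  # below E_Hb
  expect_identical(pw_e$p_A, 0)
  # starvation (negative growth) is flagged
  expect_error(deb_powers(p, E = 0.01 * E_m, L = 1, E_H = p$E_Hp),
               "negative growth")
})

test_that("initial reserve matches the fine-grid oracle and the maternal effect", {
  p <- reference_params()
  ir <- ref_E0()
  expect_equal(ir$E_0, oracle$E_0, tolerance = 1e-6)
  expect_equal(ir$a_b, oracle$a_b, tolerance = 1e-5)
  expect_equal(ir$L_b, oracle$L_b, tolerance = 1e-5)
  expect_lt(abs(ir$e_b - 1), 1e-6)
  # lower food of the mother -> cheaper egg
  ir08 <- initial_reserve(p, f = 0.8)
  expect_lt(ir08$E_0, ir$E_0)
  expect_lt(abs(ir08$e_b - 0.8), 1e-6)
  # more maturation to reach -> strictly more reserve
  E0s <- vapply(c(0.2, 0.275, 0.4, 0.6),
                function(eh) initial_reserve(reference_params(E_Hb = eh))$E_0,
                numeric(1))
  expect_true(all(diff(E0s) > 0))
})

test_that("results are insensitive to the embryo structure seed", {
  p <- reference_params()
  i1 <- initial_reserve(p, L_seed = 1e-4)
  i2 <- initial_reserve(p, L_seed = 5e-5)
  expect_lt(abs(i1$E_0 - i2$E_0) / i1$E_0, 1e-6)
  expect_lt(abs(i1$a_b - i2$a_b) / i1$a_b, 1e-6)
})

test_that("reserve density stays at f after birth (homeostasis at equilibrium)", {
  st <- ref_traj()$states
  p <- reference_params()
  post <- st[st$E_H >= p$E_Hb, ]
  e <- post$E / (post$L^3 * (p$p_Am / p$v))
  expect_lt(max(abs(e - 1)), 1e-6)
})

test_that("growth follows the closed-form von Bertalanffy solution", {
  r_B <- ref_r_B()
  tr <- ref_traj()
  ab <- tr$events$a[tr$events$event == "birth"]
  Lb <- tr$events$L[tr$events$event == "birth"]
  post <- tr$states[tr$states$a > ab & tr$states$stage >= 3, ]
  L_closed <- 1 - (1 - Lb) * exp(-r_B * (post$a - ab))
  expect_lt(max(abs(post$L - L_closed) / L_closed), 1e-6)
  # abj: same r_B after acceleration, asymptote s_M * L_m
  ta <- abj_traj()
  aj <- ta$events$a[ta$events$event == "metamorphosis"]
  Lj <- ta$events$L[ta$events$event == "metamorphosis"]
  L_inf <- ta$s_M * 1
  postj <- ta$states[ta$states$a > aj & ta$states$stage >= 3, ]
  Lj_closed <- L_inf - (L_inf - Lj) * exp(-r_B * (postj$a - aj))
  expect_lt(max(abs(postj$L - Lj_closed)), 1e-8)
  # asymptote reached at the default horizon
  expect_equal(tr$states$L[nrow(tr$states)], 1, tolerance = 1e-4)
})

test_that("reserve balance: E(a2) - E(a1) equals the integrated net flux", {
  # checked per life stage (the net flux has a kink at birth, so a trapezoid
  # across stage boundaries would measure grid error, not solver error);
  # a dense output grid keeps the quadrature error below the bound
  st <- deb_simulate(reference_params(), hazard = hazard_config(aging = FALSE),
                     n_out = 2000)$states
  for (sg in unique(st$stage)) {
    s <- st[st$stage == sg, ]
    if (nrow(s) < 10) next
    net <- s$p_A - s$p_C
    intE <- cumsum(c(0, diff(s$a) * (head(net, -1) + tail(net, -1)) / 2))
    expect_lt(max(abs((s$E - s$E[1]) - intE)) / max(st$E), 2e-5,
              label = sprintf("stage %d reserve balance", sg))
  }
})

test_that("monotonicity: L and E_H non-decreasing, S non-increasing", {
  tr <- deb_simulate(reference_params(), hazard = hazard_config(aging = TRUE))
  st <- tr$states
  expect_true(all(diff(st$L) > -1e-12))
  expect_true(all(diff(st$E_H) > -1e-8))
  expect_true(all(diff(st$S) < 1e-12))
  expect_true(all(st$E_H <= reference_params()$E_Hp + 1e-9))
})

test_that("event ages increase and the std model has no metamorphosis event", {
  tr <- ref_traj()
  expect_false("metamorphosis" %in% tr$events$event)
  ta <- abj_traj()
  expect_identical(ta$events$event, c("birth", "metamorphosis", "puberty"))
  expect_true(all(diff(ta$events$a) > 0))
  # acceleration factor s_M = L_j / L_b
  expect_equal(ta$s_M, ta$events$L[2] / ta$events$L[1])
})

test_that("abj with E_Hj = E_Hb degenerates exactly to std", {
  p_std <- reference_params()
  p_abj <- reference_params(model = "abj", E_Hj = p_std$E_Hb)
  t_std <- deb_simulate(p_std, hazard = hazard_config(aging = FALSE))
  t_abj <- deb_simulate(p_abj, hazard = hazard_config(aging = FALSE))
  expect_identical(t_abj$s_M, 1)
  # compare states at common ages
  L_abj <- approx(t_abj$states$a, t_abj$states$L, xout = t_std$states$a)$y
  expect_lt(max(abs(L_abj - t_std$states$L) / t_std$states$L, na.rm = TRUE), 1e-9)
  E_abj <- approx(t_abj$states$a, t_abj$states$E, xout = t_std$states$a)$y
  expect_lt(max(abs(E_abj - t_std$states$E) / pmax(t_std$states$E, 1e-6),
                na.rm = TRUE), 1e-8)
})

test_that("aging at fixed size integrates to the closed-form Weibull survival", {
  # fully grown adult, s_G = 0: q = h_a e v a / L, h = q a / 2,
  # S = exp(-h_a e v a^3 / (6 L))
  p <- reference_params(s_G = 0)
  hz <- hazard_config(aging = TRUE)
  ct <- debtraits:::.deb_ct(p, 1, hz, stage = 4L, s_M = 1)
  y0 <- c(E = 1125, L = 1, E_H = 166, E_R = 0, q = 0, h = 0, H = 0)
  times <- seq(0, 800, by = 4)
  out <- deSolve::lsoda(y0, times, debtraits:::.deb_rhs, ct,
                        rtol = 1e-10, atol = 1e-12)
  S_num <- exp(-out[, 8])
  S_closed <- exp(-p$h_a * 1 * p$v * times^3 / 6)
  expect_lt(max(abs(S_num - S_closed) / S_closed), 1e-6)
})

test_that("unreachable maturity is reported as such", {
  # maturity maintenance ceiling: k_J E_Hp exceeds (1-kap) p_A at L_inf,
  # while birth (k_J E_Hb small) stays reachable
  p <- reference_params(k_J = 0.03)
  expect_error(deb_simulate(p, end = "puberty"), "unreachable puberty")
  # birth unreachable: maintenance swallows mobilization before E_Hb
  p2 <- reference_params(k_J = 5, E_Hb = 50, E_Hp = 166)
  expect_error(initial_reserve(p2), "unreachable birth")
})
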