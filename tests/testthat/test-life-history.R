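test_that("life events match the fine-grid oracle and basic orderings", {
  p <- reference_params()
  le <- life_events(p)
  expect_equal(le$a_b, oracle$a_b, tolerance = 1e-4)
  expect_equal(le$L_b, oracle$L_b, tolerance = 1e-5)
  expect_equal(le$a_p, oracle$a_p, tolerance = 1e-4)
  expect_equal(le$L_p, oracle$L_p, tolerance = 1e-5)
  expect_identical(le$s_M, 1)          # std
  expect_equal(le$L_inf, 1)
  expect_true(le$a_b < le$a_p)
  expect_true(le$L_b < le$L_p && le$L_p < le$L_inf)
  expect_true(le$W_b < le$W_p && le$W_p < le$W_inf)
})

test_that("acceleration factor: degenerate abj gives 1, ratio of lengths otherwise", {
  p1 <- reference_params(model = "abj", E_Hj = reference_params()$E_Hb)
  expect_identical(life_events(p1)$s_M, 1)
  le <- life_events(abj_params(), traj = abj_traj())
  expect_equal(le$s_M, le$L_j / le$L_b)
  expect_gt(le$s_M, 1)
  expect_equal(le$L_inf, le$s_M * 1)   # L_inf = s_M f L_m
})

test_that("supply stress: formula value, flux identity, homogeneity and bound", {
  p <- reference_params()
  s <- supply_stress(p)
  expect_equal(s, 0.002 * 166 * 18^2 / 22.5^3)   # ~0.00944
  # identity with p_J p_S^2 / p_A^3 at ultimate size
  E_m <- p$p_Am / p$v
  pw <- deb_powers(p, E = E_m, L = 1, E_H = p$E_Hp)
  expect_lt(abs(s - pw$p_J * pw$p_S^2 / pw$p_A^3) / s, 1e-12)
  # waste-to-hurry homogeneity: joint doubling of p_Am and p_M halves s_s
  p2 <- reference_params(p_Am = 45, p_M = 36)
  expect_equal(supply_stress(p2), s / 2, tolerance = 1e-12)
  # bound s_s <= kap^2 (1 - kap) <= 4/27 over random viable draws
  set.seed(42)
  for (i in 1:200) {
    kap <- runif(1, 0.1, 0.95)
    z <- 10^runif(1, -1, 1)
    k_J <- 0.002 * 10^runif(1, -0.5, 0.5)
    p_Am <- z * 18 / kap
    L_inf <- kap * p_Am / 18
    E_Hp_max <- (1 - kap) * p_Am * L_inf^2 / k_J
    E_Hp <- runif(1, 0.01, 0.99) * E_Hp_max   # viable: below the ceiling
    pr <- reference_params(kap = kap, p_Am = p_Am, k_J = k_J, E_Hp = E_Hp,
                           E_Hb = min(0.275 * z^3, E_Hp / 2))
    ss <- supply_stress(pr, s_M = 1)
    expect_lte(ss, kap^2 * (1 - kap) + 1e-12)
    expect_lte(ss, 4 / 27 + 1e-12)
    expect_gt(ss, 0)
  }
})

test_that("maturation-ceiling family attains 4/27 at kap = 2/3", {
  grid <- supply_stress_ceiling(seq(1e-4, 1 - 1e-4, by = 1e-4))
  i <- which.max(grid$s_s)
  expect_equal(grid$kap[i], 2 / 3, tolerance = 1e-4)
  expect_equal(grid$s_s[i], 4 / 27, tolerance = 1e-7)
})

test_that("precociality is the maturity ratio, strictly inside (0,1)", {
  p <- reference_params()
  expect_equal(precociality(p), 0.275 / 166)
  expect_error(precociality(reference_params(E_Hb = 166)), "E_Hb")
  # limit towards extreme precocial
  expect_gt(precociality(reference_params(E_Hb = 166 - 1e-9)), 1 - 1e-10)
})

test_that("reproduction declines towards kap = 1 and with higher E_Hp", {
  R9 <- reproduction_rate(reference_params(kap = 0.9))
  R98 <- reproduction_rate(reference_params(kap = 0.98))
  expect_gt(R9, R98)
  R_hi <- reproduction_rate(reference_params(E_Hp = 332))
  expect_lt(R_hi, reproduction_rate(reference_params()))
  # nothing left at the maturation ceiling -> zero with a warning
  p0 <- reference_params(k_J = 0.028)  # just above (1-kap) p_Am L_inf^2 / E_Hp
  expect_warning(R0 <- reproduction_rate(p0, E_0 = 1.8), "no positive reproduction")
  expect_identical(R0, 0)
})

test_that("allocation fraction equals maintenance over assimilation when fully grown", {
  set.seed(7)
  for (kap in c(0.3, 0.55, 0.8, 0.95)) {
    p <- reference_params(kap = kap, E_Hp = 166 * kap)
    E_m <- p$p_Am / p$v
    L_inf <- kap * p$p_Am / p$p_M
    pw <- deb_powers(p, E = E_m * L_inf^3, L = L_inf, E_H = p$E_Hp)
    expect_equal(pw$p_S / pw$p_A, kap, tolerance = 1e-12)
  }
})

test_that("lifespan: oracle regression, Weibull scaling in h_a, continuity in s_G", {
  p <- reference_params()
  expect_equal(lifespan(p)$a_m, oracle$a_m, tolerance = 1e-3)
  # a_m ~ h_a^(-1/3) when lifespan is long relative to growth (s_G = 0);
  # the growth period contributes a slowly vanishing correction, hence 10%
  a1 <- lifespan(reference_params(s_G = 0, h_a = 1e-9))$a_m
  a8 <- lifespan(reference_params(s_G = 0, h_a = 8e-9))$a_m
  expect_equal(a8 / a1, 0.5, tolerance = 0.1)
  # continuity at s_G -> 0
  am0 <- lifespan(reference_params(s_G = 1e-9))$a_m
  am6 <- lifespan(reference_params(s_G = 1e-6))$a_m
  expect_lt(abs(am0 - am6) / am0, 1e-3)
})

test_that("lifetime output: fewer neonates under faster aging, same order as W_inf", {
  p <- reference_params()
  lo <- lifetime_output(p)
  expect_gt(lo$N_inf, 0)
  lo_fast <- lifetime_output(reference_params(h_a = 1e-5))
  expect_lt(lo_fast$N_inf, lo$N_inf)
  # lifetime neonate mass of the same order of magnitude as ultimate weight
  W_inf <- life_events(p)$W_inf
  expect_gt(lo$NWb / W_inf, 0.01)
  expect_lt(lo$NWb / W_inf, 10)
})

test_that("maximum specific growth: 1.5 r_B at two-thirds of ultimate length", {
  p <- reference_params()
  mg <- max_specific_growth(p, traj = ref_traj())
  r_B <- ref_r_B()
  # reserve-free von Bertalanffy analysis: max of dW/da at L = (2/3) L_inf,
  # r_m = 3 r_B (L_inf/L - 1) = 1.5 r_B
  expect_equal(mg$r_m, 1.5 * r_B, tolerance = 0.15)
  st <- ref_traj()$states
  L_at <- approx(st$a, st$L, xout = mg$a_at_max)$y
  expect_equal(L_at, 2 / 3, tolerance = 0.01)
})

test_that("waste-to-hurry: joint raise of assimilation and maintenance keeps size
           and boosts growth and reproduction; aging as such is untouched", {
  p1 <- reference_params()
  p3 <- reference_params(p_Am = 3 * 22.5, p_M = 3 * 18)
  le1 <- life_events(p1); le3 <- life_events(p3)
  expect_equal(le3$L_inf, le1$L_inf, tolerance = 1e-12)   # L_inf unchanged
  mg1 <- max_specific_growth(p1); mg3 <- max_specific_growth(p3)
  expect_gt(mg3$r_m, 1.5 * mg1$r_m)                       # faster growth
  expect_gt(reproduction_rate(p3), reproduction_rate(p1)) # boosted reproduction
  # the aging module does not transmit maintenance: damage induction
  # h_a e (v/L - r) is unchanged at equal length, so lifespan barely moves
  # (slightly up, via the shorter transient at small L)
  a1 <- lifespan(p1)$a_m; a3 <- lifespan(p3)$a_m
  expect_lt(abs(a3 - a1) / a1, 0.1)
})

test_that("weight-specific respiration falls with size, slope in (-1/3, 0)", {
  zs <- 10^seq(-0.6, 1.2, length.out = 12)
  rows <- t(vapply(zs, function(z) {
    p <- reference_params(p_Am = z * 22.5, E_Hb = 0.275 * z^3,
                          E_Hp = 166 * z^3)
    cmp <- compound_parameters(p)
    W_inf <- wet_weight(p, cmp$L_m, cmp$E_m * cmp$L_m^3)
    c(W_inf = W_inf, jO = weight_specific_respiration(p, s_M = 1))
  }, numeric(2)))
  expect_true(all(diff(rows[, "jO"]) < 0))   # bigger species respire less per gram
  fit <- loglog_fit(rows[, "W_inf"], rows[, "jO"])
  expect_gt(fit$slope, -1 / 3)
  expect_lt(fit$slope, 0)
})

test_that("trait record assembles consistently", {
  p <- reference_params()
  tr <- trait_record(p, compute_r_N = FALSE)
  expect_identical(tr$s_M, 1)
  expect_equal(tr$E_m, 1125)
  expect_equal(tr$s_s, supply_stress(p))
  expect_equal(tr$s_Hbp, precociality(p))
  expect_equal(tr$jWb_i, tr$R_i * tr$Ww_b / tr$Ww_i, tolerance = 1e-12)
  expect_true(tr$a_b < tr$a_p && tr$a_p < tr$a_m)
})
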