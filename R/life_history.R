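# Derivation of life-history traits from a primary parameter set at constant
# scaled functional response and reference temperature.

#' Ages, lengths and weights at life events
#'
#' Runs the life cycle to puberty and extracts ages, structural lengths and
#' wet weights at birth, metamorphosis (abj) and puberty, the acceleration
#' factor \eqn{s_M = L_j/L_b} (1 for std) and the ultimate size
#' \eqn{L_\infty = s_M (f L_m - L_T)}.
#'
#' @param p a \code{\link{deb_params}} object.
#' @param f scaled functional response (default \code{p$f}).
#' @param traj optionally, a precomputed \code{\link{deb_simulate}} trajectory
#'   containing the puberty event.
#' @return list with \code{a_b}, \code{a_j}, \code{a_p} (d), \code{L_b},
#'   \code{L_j}, \code{L_p}, \code{L_inf} (cm), \code{W_b}, \code{W_p},
#'   \code{W_inf} (g wet), \code{s_M}, \code{E_0} (J).
#' @export
life_events <- function(p, f = p$f, traj = NULL) {
  if (is.null(traj)) traj <- deb_simulate(p, f = f, end = "puberty")
  ev <- traj$events
  get_ev <- function(name, col) {
    i <- match(name, ev$event)
    if (is.na(i)) NA_real_ else ev[[col]][i]
  }
  if (is.na(match("puberty", ev$event)))
    stop(sprintf("unreachable puberty for '%s'", p$species_id), call. = FALSE)
  cmp <- compound_parameters(p)
  s_M <- traj$s_M
  L_inf <- s_M * (f * cmp$L_m - cmp$L_T)
  W_inf <- wet_weight(p, L_inf, f * cmp$E_m * L_inf^3)
  a_j <- get_ev("metamorphosis", "a")
  L_j <- get_ev("metamorphosis", "L")
  if (p$model == "std") { a_j <- get_ev("birth", "a"); L_j <- get_ev("birth", "L") }
  list(a_b = get_ev("birth", "a"), a_j = a_j, a_p = get_ev("puberty", "a"),
       L_b = get_ev("birth", "L"), L_j = L_j, L_p = get_ev("puberty", "L"),
       L_inf = L_inf,
       W_b = get_ev("birth", "W_w"), W_p = get_ev("puberty", "W_w"),
       W_inf = W_inf, s_M = s_M, E_0 = traj$E_0)
}

#' Supply stress
#'
#' The dimensionless position of a species on the supply--demand spectrum,
#' \deqn{s_s = \dot k_J E_H^p [p_M]^2 / (f^3 s_M^3 \{p_{Am}\}^3),}
#' which equals \eqn{p_J p_S^2 / p_A^3} evaluated at ultimate size.  It lies
#' in (0, 4/27]; the maximum 4/27 is attained at the maturation ceiling
#' (\eqn{p_R \to 0}) with \eqn{\kappa = 2/3}.
#'
#' @inheritParams life_events
#' @param s_M acceleration factor; 1 for std, computed via
#'   \code{\link{life_events}} for abj when NULL.
#' @return supply stress, dimensionless.
#' @export
supply_stress <- function(p, f = p$f, s_M = NULL) {
  validate_deb_params(p)
  if (is.null(s_M)) s_M <- if (p$model == "std") 1 else life_events(p, f)$s_M
  p$k_J * p$E_Hp * p$p_M^2 / (f^3 * s_M^3 * p$p_Am^3)
}

#' Supply stress along the maturation-ceiling family
#'
#' For each allocation fraction on the grid, constructs a parameter set whose
#' puberty threshold sits exactly at the maturation ceiling (allocation to
#' reproduction vanishes at ultimate size: \eqn{k_J E_H^p = (1-\kappa)
#' p_A(L_\infty)}) and evaluates the supply stress.  Along this family
#' \eqn{s_s = \kappa^2 (1 - \kappa)}, maximal at \eqn{\kappa = 2/3}.
#'
#' @param kap vector of allocation fractions in (0,1).
#' @param p template parameter set (default \code{\link{reference_params}}).
#' @param f scaled functional response.
#' @return data.frame with columns \code{kap}, \code{s_s}.
#' @export
supply_stress_ceiling <- function(kap, p = reference_params(), f = 1) {
  stopifnot(all(kap > 0), all(kap < 1))
  s_s <- vapply(kap, function(k) {
    L_inf <- f * k * p$p_Am / p$p_M
    p_A_inf <- f * p$p_Am * L_inf^2
    E_Hp_ceiling <- (1 - k) * p_A_inf / p$k_J
    pk <- p
    pk$kap <- k
    pk$E_Hp <- E_Hp_ceiling
    pk$E_Hb <- min(pk$E_Hb, E_Hp_ceiling / 2)
    pk$E_Hj <- pk$E_Hb
    supply_stress(pk, f = f, s_M = 1)
  }, numeric(1))
  data.frame(kap = kap, s_s = s_s)
}

#' Precociality coefficient
#'
#' \eqn{s_H^{bp} = E_H^b / E_H^p}: the ratio of maturity at birth to maturity
#' at puberty, between 0 (extreme altricial) and 1 (extreme precocial).
#'
#' @param p a \code{\link{deb_params}} object.
#' @return dimensionless ratio in (0,1).
#' @export
precociality <- function(p) {
  validate_deb_params(p)
  if (p$E_Hb >= p$E_Hp)
    stop("precociality undefined: E_Hb must be below E_Hp", call. = FALSE)
  p$E_Hb / p$E_Hp
}

#' Maximum reproduction rate at ultimate size
#'
#' Continuous egg production rate of a fully grown adult,
#' \eqn{R_\infty = \kappa_R \, p_R(L_\infty) / E_0}, with \eqn{E_0} the egg
#' cost from \code{\link{initial_reserve}}.
#'
#' @inheritParams life_events
#' @param E_0 egg cost, J (computed when NULL).
#' @param s_M acceleration factor (computed for abj when NULL).
#' @return eggs per day.  Zero (with a warning) when nothing remains for
#'   reproduction at ultimate size.
#' @export
reproduction_rate <- function(p, f = p$f, E_0 = NULL, s_M = NULL) {
  validate_deb_params(p)
  if (is.null(s_M)) s_M <- if (p$model == "std") 1 else life_events(p, f)$s_M
  cmp <- compound_parameters(p)
  L_inf <- s_M * (f * cmp$L_m - cmp$L_T)
  pw <- deb_powers(p, E = f * cmp$E_m * L_inf^3, L = L_inf, E_H = p$E_Hp,
                   f = f, s_acc = s_M, allow_negative_growth = TRUE)
  if (pw$p_R <= 0) {
    warning(sprintf("no positive reproduction flux at ultimate size for '%s'",
                    p$species_id))
    return(0)
  }
  if (is.null(E_0)) E_0 <- initial_reserve(p, f)$E_0
  p$kap_R * pw$p_R / E_0
}

# trapezoid integral
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Expected lifespan under aging
#'
#' Mean age at death from the Weibull-Gompertz aging module at constant food,
#' with no background or thinning hazard: \eqn{a_m = \int_0^\infty S(a)\,da},
#' truncated once survival falls below \code{S_min} with an exponential tail
#' correction.
#'
#' @inheritParams life_events
#' @param S_min truncation level of the survival function (default 1e-6).
#' @param traj optional precomputed trajectory with aging hazard and
#'   \code{until_S = S_min}.
#' @return list with \code{a_m} (d) and the survival curve as a data.frame
#'   \code{S_a} with columns \code{a}, \code{S}.
#' @export
lifespan <- function(p, f = p$f, S_min = 1e-6, traj = NULL) {
  if (is.null(traj)) traj <- .simulate_until_S(p, f, S_min,
                                               hazard_config(aging = TRUE))
  st <- traj$states
  a_m <- .trapz(st$a, st$S)
  h_end <- st$h[nrow(st)]
  if (st$S[nrow(st)] > 0 && h_end > 0)
    a_m <- a_m + st$S[nrow(st)] / h_end   # exponential tail
  list(a_m = a_m, S_a = data.frame(a = st$a, S = st$S))
}

# integrate with doubling horizon until survival drops below S_min
.simulate_until_S <- function(p, f, S_min, hazard, E_0 = NULL, n_out = 500) {
  cmp <- compound_parameters(p)
  r_B <- cmp$k_M * cmp$g / (3 * (f + cmp$g))
  horizon <- 25 / r_B
  if (is.null(E_0)) E_0 <- initial_reserve(p, f)$E_0
  for (i in 1:12) {
    traj <- suppressWarnings(
      deb_simulate(p, f = f, horizon = horizon, E_0 = E_0, hazard = hazard,
                   until_S = S_min, n_out = n_out))
    if (traj$states$S[nrow(traj$states)] <= S_min * 1.0001) return(traj)
    horizon <- horizon * 2
  }
  warning("survival did not reach S_min within the maximum horizon")
  traj
}

#' Lifetime reproductive output and lifetime neonate mass
#'
#' \eqn{N_\infty = \int_0^\infty S(a) R(a)\,da}, the expected number of
#' neonates over a lifetime under pure aging mortality, and the lifetime
#' neonate mass \eqn{N_\infty W_w^b}.
#'
#' @inheritParams lifespan
#' @return list with \code{N_inf} (neonates), \code{NWb} (g),
#'   \code{W_b} (g).
#' @export
lifetime_output <- function(p, f = p$f, S_min = 1e-6, traj = NULL) {
  if (is.null(traj)) traj <- .simulate_until_S(p, f, S_min,
                                               hazard_config(aging = TRUE))
  st <- traj$states
  R <- ifelse(st$stage == 4, pmax(st$p_R, 0) * p$kap_R / traj$E_0, 0)
  N_inf <- .trapz(st$a, st$S * R)
  i_b <- match("birth", traj$events$event)
  W_b <- traj$events$W_w[i_b]
  list(N_inf = N_inf, NWb = N_inf * W_b, W_b = W_b)
}

#' Specific body growth rate at maximum growth
#'
#' Locates the age at which the wet-weight growth rate \eqn{dW_w/da} of the
#' body (structure plus reserve, excluding the reproduction buffer) is
#' maximal and returns the specific rate \eqn{r_m = (dW_w/da)/W_w} there,
#' together with the weight at maximum growth.  The weight derivative is
#' evaluated analytically from the energy fluxes along the trajectory.
#'
#' @inheritParams life_events
#' @return list with \code{r_m} (1/d), \code{W_at_max} (g), \code{a_at_max}
#'   (d).
#' @export
max_specific_growth <- function(p, f = p$f, traj = NULL) {
  if (is.null(traj))
    traj <- deb_simulate(p, f = f, hazard = hazard_config(aging = FALSE))
  st <- traj$states
  cc <- p$composition
  post <- st[st$stage >= 2 | st$E_H >= p$E_Hb, , drop = FALSE]
  dL <- post$p_G / (3 * p$E_G * post$L^2)
  W  <- cc$d_Vw * post$L^3 + post$E * cc$w_E / (cc$mu_E * cc$dwr)
  dW <- 3 * cc$d_Vw * post$L^2 * dL + (post$p_A - post$p_C) * cc$w_E / (cc$mu_E * cc$dwr)
  i <- which.max(dW)
  # quadratic refinement around the grid maximum
  if (i > 1 && i < length(dW)) {
    aa <- post$a[(i - 1):(i + 1)]; yy <- dW[(i - 1):(i + 1)]
    den <- (aa[1] - aa[2]) * (aa[1] - aa[3]) * (aa[2] - aa[3])
    A <- (aa[3] * (yy[2] - yy[1]) + aa[2] * (yy[1] - yy[3]) + aa[1] * (yy[3] - yy[2])) / den
    B <- (aa[3]^2 * (yy[1] - yy[2]) + aa[2]^2 * (yy[3] - yy[1]) + aa[1]^2 * (yy[2] - yy[3])) / den
    a_star <- if (A < 0) -B / (2 * A) else post$a[i]
    a_star <- min(max(a_star, aa[1]), aa[3])
  } else a_star <- post$a[i]
  r_of <- function(a) {
    j <- findInterval(a, post$a, all.inside = TRUE)
    w <- (a - post$a[j]) / (post$a[j + 1] - post$a[j])
    dWa <- (1 - w) * dW[j] + w * dW[j + 1]
    Wa  <- (1 - w) * W[j] + w * W[j + 1]
    c(dWa / Wa, Wa)
  }
  rr <- r_of(a_star)
  list(r_m = rr[1], W_at_max = rr[2], a_at_max = a_star)
}

#' Weight-specific oxygen consumption at ultimate size
#'
#' Respiration of a fully grown adult at constant food divided by its wet
#' weight, mol O2 / d / g.
#'
#' @inheritParams reproduction_rate
#' @return mol O2 per day per gram wet weight.
#' @export
weight_specific_respiration <- function(p, f = p$f, s_M = NULL) {
  validate_deb_params(p)
  if (is.null(s_M)) s_M <- if (p$model == "std") 1 else life_events(p, f)$s_M
  cmp <- compound_parameters(p)
  L_inf <- s_M * (f * cmp$L_m - cmp$L_T)
  E_inf <- f * cmp$E_m * L_inf^3
  J_O2 <- deb_respiration(p, E = E_inf, L = L_inf, E_H = p$E_Hp, f = f,
                          s_acc = s_M)
  J_O2 / wet_weight(p, L_inf, E_inf)
}

#' Full life-history trait record of a species
#'
#' Derives the complete trait vector of a species from its primary
#' parameters at constant scaled functional response: compound parameters,
#' acceleration factor, precociality, supply stress, ages, lengths and wet
#' weights at life events and ultimate size, lifespan, maximum reproduction
#' rate, lifetime neonate mass, maximum specific body growth rate, specific
#' population growth rate under thinning and weight-specific respiration.
#' Rates and times are reported at temperature \code{T} (default the
#' reference temperature of the parameters, conventionally 20 C);
#' dimensionless traits are temperature-invariant.
#'
#' @inheritParams life_events
#' @param T temperature at which rates/times are reported, K.
#' @param thinning include thinning in the population growth rate
#'   (default TRUE).
#' @param compute_r_N set FALSE to skip the (comparatively expensive)
#'   population growth rate; the column is then NA.
#' @return one-row data.frame with columns \code{species_id}, \code{taxon},
#'   \code{model}, \code{E_m}, \code{L_m}, \code{s_M}, \code{s_Hbp},
#'   \code{s_s}, \code{a_b}, \code{a_p}, \code{a_m}, \code{Ww_b},
#'   \code{Ww_p}, \code{Ww_i}, \code{L_b}, \code{L_p}, \code{L_i},
#'   \code{E_Hb}, \code{E_Hp}, \code{kap}, \code{p_M}, \code{v}, \code{r_N},
#'   \code{r_m}, \code{jO_i}, \code{R_i}, \code{NWb}, \code{jWb_i}.
#'   \code{jWb_i} is the neonate mass production rate \eqn{R_\infty W_w^b /
#'   W_w^\infty} in g/d/g; the dimensionless lifetime form \eqn{N_\infty
#'   W_w^b / W_w^\infty} is reported alongside as \code{NWb_Wi}.
#' @export
trait_record <- function(p, f = p$f, T = p$T_ref, thinning = TRUE,
                         compute_r_N = TRUE) {
  validate_deb_params(p)
  cmp <- compound_parameters(p)
  ir <- initial_reserve(p, f)
  traj <- .simulate_until_S(p, f, S_min = 1e-6, hazard_config(aging = TRUE),
                            E_0 = ir$E_0)
  le <- life_events(p, f, traj = traj)
  ls <- lifespan(p, f, traj = traj)
  lo <- lifetime_output(p, f, traj = traj)
  mg <- max_specific_growth(p, f, traj = traj)
  R_i <- suppressWarnings(reproduction_rate(p, f, E_0 = ir$E_0, s_M = le$s_M))
  jO <- weight_specific_respiration(p, f, s_M = le$s_M)
  r_N <- if (compute_r_N) {
    pg <- try(population_growth_rate(
      p, f, hazard = hazard_config(aging = TRUE, thinning = thinning),
      E_0 = ir$E_0), silent = TRUE)
    if (inherits(pg, "try-error")) NA_real_ else pg$r_N
  } else NA_real_
  c_T <- exp(p$T_A / p$T_ref - p$T_A / T)
  rate <- function(x) x * c_T
  time <- function(x) x / c_T
  data.frame(species_id = p$species_id, taxon = p$taxon, model = p$model,
             E_m = cmp$E_m, L_m = cmp$L_m, s_M = le$s_M,
             s_Hbp = precociality(p),
             s_s = supply_stress(p, f, s_M = le$s_M),
             a_b = time(le$a_b), a_p = time(le$a_p), a_m = time(ls$a_m),
             Ww_b = le$W_b, Ww_p = le$W_p, Ww_i = le$W_inf,
             L_b = le$L_b, L_p = le$L_p, L_i = le$L_inf,
             E_Hb = p$E_Hb, E_Hp = p$E_Hp, kap = p$kap, p_M = rate(p$p_M),
             v = rate(p$v),
             r_N = rate(r_N), r_m = rate(mg$r_m), jO_i = rate(jO),
             R_i = rate(R_i), NWb = lo$NWb,
             jWb_i = rate(R_i * le$W_b / le$W_inf),
             NWb_Wi = lo$NWb / le$W_inf,
             stringsAsFactors = FALSE)
}

#' Trait table for a set of species
#'
#' Applies \code{\link{trait_record}} to every row of a parameter table.
#' Failures (non-viable parameter sets) are collected and reported; the
#' corresponding rows are dropped with a warning.
#'
#' @param params list of \code{\link{deb_params}} objects, or a data.frame in
#'   the parameter-file schema (see \code{\link{read_deb_params}}).
#' @inheritParams trait_record
#' @param verbose print per-species progress.
#' @return data.frame of trait records (class \code{trait_table}).
#' @export
trait_table <- function(params, f = NULL, T = NULL, thinning = TRUE,
                        compute_r_N = TRUE, verbose = FALSE) {
  if (is.data.frame(params)) params <- params_from_table(params)
  rows <- list(); fails <- character()
  for (p in params) {
    t0 <- Sys.time()
    row <- try(trait_record(p, f = if (is.null(f)) p$f else f,
                            T = if (is.null(T)) p$T_ref else T,
                            thinning = thinning, compute_r_N = compute_r_N),
               silent = TRUE)
    if (inherits(row, "try-error")) {
      fails <- c(fails, sprintf("%s: %s", p$species_id,
                                trimws(attr(row, "condition")$message)))
    } else {
      rows[[length(rows) + 1L]] <- row
    }
    if (verbose)
      message(sprintf("%s: %s (%.2fs)", p$species_id,
                      if (inherits(row, "try-error")) "FAILED" else "ok",
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  if (length(fails))
    warning(sprintf("%d species failed:\n%s", length(fails),
                    paste(fails, collapse = "\n")))
  out <- do.call(rbind, rows)
  class(out) <- c("trait_table", "data.frame")
  attr(out, "failures") <- fails
  out
}
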