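# Specific population growth rate under thinning via the Euler-Lotka
# characteristic equation.

#' Thinning hazard along a trajectory
#'
#' Thinning keeps the total feeding rate of a cohort constant under constant
#' conditions: individual intake scales with (accelerated) squared length, so
#' numbers must fall as \eqn{h_{thin} = d\,\ln(s_{acc} L^2)/da}, i.e.
#' \eqn{2 \dot L/L} after acceleration and \eqn{3 \dot L/L} during it (when
#' \eqn{s_{acc} = L/L_b}).
#'
#' @param traj a \code{\link{deb_trajectory}}.
#' @return function of age (d) returning the thinning hazard (1/d), linearly
#'   interpolated between solver output points (0 before birth).
#' @export
thinning_hazard <- function(traj) {
  st <- traj$states
  p <- traj$params
  dL <- st$p_G / (3 * p$E_G * st$L^2)
  mult <- ifelse(st$stage == 2, 3, 2)   # during acceleration s_acc = L/L_b
  h <- ifelse(st$stage >= 2, mult * pmax(dL, 0) / st$L, 0)   # none before birth
  stats::approxfun(st$a, h, rule = 2)
}

#' Specific population growth rate
#'
#' Solves the Euler-Lotka characteristic equation
#' \deqn{1 = \int_0^\infty e^{-r a} S(a) R(a)\, da}
#' for the specific population growth rate \eqn{r_N}, where \eqn{S} is
#' survival under the configured hazards (aging, thinning, background) and
#' \eqn{R(a) = \kappa_R p_R(a)/E_0} is the continuous reproduction rate (zero
#' before puberty).  The left-hand integral is monotone decreasing in
#' \eqn{r}, so the root is unique; it is located by bracketing and root
#' refinement with the residual reported.
#'
#' @param p a \code{\link{deb_params}} object.
#' @param f scaled functional response.
#' @param hazard a \code{\link{hazard_config}}; default aging plus thinning.
#' @param E_0 egg cost, J (computed when NULL).
#' @param S_min integrate the schedule until survival times peak reproduction
#'   falls below this fraction (default 1e-12 of peak) or survival is below
#'   1e-10.
#' @param bracket initial bracket for the root, 1/d.
#' @return list of class \code{population_growth}: \code{r_N} (1/d),
#'   \code{residual}, \code{horizon} (d), \code{R_0} (net reproduction
#'   number).
#' @export
population_growth_rate <- function(p, f = p$f,
                                   hazard = hazard_config(aging = TRUE,
                                                          thinning = TRUE),
                                   E_0 = NULL, S_min = 1e-10,
                                   bracket = c(-0.5, 5)) {
  validate_deb_params(p)
  if (is.null(E_0)) E_0 <- initial_reserve(p, f)$E_0
  traj <- .simulate_until_S(p, f, S_min = S_min, hazard = hazard, E_0 = E_0,
                            n_out = 800)
  st <- traj$states
  R <- ifelse(st$stage == 4, pmax(st$p_R, 0) * p$kap_R / E_0, 0)
  a <- st$a; SR <- st$S * R
  R_0 <- .trapz(a, SR)
  if (all(R <= 0) || R_0 <= 0)
    stop(sprintf("sub-replacement, no positive root for '%s': no surviving reproduction",
                 p$species_id), call. = FALSE)
  if (R_0 <= 1)
    warning(sprintf("sub-replacement for '%s' (R_0 = %.3g): no positive root, returning the negative one",
                    p$species_id, R_0))
  root <- .euler_lotka_root(a, SR, bracket)
  out <- list(r_N = root$r_N, residual = root$residual,
              horizon = max(a), R_0 = R_0)
  class(out) <- "population_growth"
  out
}

# shared root finder on the discounted schedule; the integrand is evaluated in
# log space (with a generous clamp far from the root) so very small survival
# values cannot overflow the discount factor
.euler_lotka_root <- function(a, SR, bracket = c(-0.5, 5)) {
  lsr <- ifelse(SR > 0, log(SR), -Inf)
  charfun <- function(r) .trapz(a, exp(pmin(-r * a + lsr, 200))) - 1
  lo <- bracket[1]; hi <- bracket[2]
  for (i in 1:60) { if (charfun(lo) > 0) break; lo <- lo * 2 }   # expand down
  for (i in 1:60) { if (charfun(hi) < 0) break; hi <- hi * 2 }   # expand up
  root <- stats::uniroot(charfun, lower = lo, upper = hi, tol = 1e-12)
  list(r_N = root$root, residual = charfun(root$root))
}

#' @export
print.population_growth <- function(x, ...) {
  cat(sprintf("specific population growth rate r_N = %.6g 1/d (R_0 = %.4g)\n",
              x$r_N, x$R_0))
  cat(sprintf("  characteristic residual %.2e over horizon %.4g d\n",
              x$residual, x$horizon))
  invisible(x)
}

#' Euler-Lotka solver for an explicit schedule
#'
#' Solves \eqn{1 = \int e^{-ra} S(a) R(a) da} for tabulated survival and
#' reproduction schedules.  Used mostly for oracle checks; the package
#' pipeline goes through \code{\link{population_growth_rate}}.
#'
#' @param a ages, d (increasing grid).
#' @param S survival at \code{a}.
#' @param R reproduction rate at \code{a}, 1/d.
#' @param bracket initial bracket, 1/d.
#' @return list with \code{r_N} and \code{residual}.
#' @export
euler_lotka <- function(a, S, R, bracket = c(-0.5, 5)) {
  stopifnot(length(a) == length(S), length(S) == length(R))
  .euler_lotka_root(a, S * R, bracket)
}
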