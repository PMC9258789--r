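# State dynamics of the std and abj DEB models.
#
# State vector used internally by the solver:
#   y = (E, L, E_H, E_R, q, h, H)
# with E reserve (J), L volumetric structural length (cm), E_H cumulated
# maturity (J), E_R reproduction buffer (J), q aging acceleration (1/d^2),
# h aging hazard (1/d) and H the cumulated total hazard, so survival
# S = exp(-H) (integrating H rather than S keeps the state well scaled when
# S underflows).  Life stages are integrated piecewise between maturity
# thresholds so the acceleration factor switches exactly at the events.

# stage codes: 1 embryo, 2 acceleration (abj only), 3 juvenile, 4 adult
.stage_s_acc <- function(stage, L, L_b, s_M) {
  if (stage == 1L) 1 else if (stage == 2L) L / L_b else s_M
}

# constant bundle handed to the right-hand side; stage-specific
.deb_ct <- function(p, f, hazard, stage, L_b = NA_real_, s_M = 1) {
  cmp <- compound_parameters(p)
  list(kap = p$kap, kap_R = p$kap_R, v = p$v, p_Am = p$p_Am, p_M = p$p_M,
       p_T = p$p_T, k_J = p$k_J, E_G = p$E_G,
       E_Hb = p$E_Hb, E_Hj = p$E_Hj, E_Hp = p$E_Hp,
       h_a = p$h_a, s_G = p$s_G,
       E_m = cmp$E_m, L_m3 = cmp$L_m^3,
       f = f, stage = stage, L_b = L_b, s_M = s_M,
       aging = hazard$aging, h_B = hazard$background,
       thinning = hazard$thinning)
}

.deb_rhs <- function(a, y, ct) {
  E <- y[1]; L <- y[2]; EH <- y[3]; q <- y[5]; h <- y[6]
  stage <- ct$stage
  L2 <- L * L; L3 <- L2 * L
  s_acc <- if (stage == 1L) 1 else if (stage == 2L) L / ct$L_b else ct$s_M
  p_A <- if (stage >= 2L) ct$f * ct$p_Am * s_acc * L2 else 0
  p_S <- ct$p_M * L3 + ct$p_T * L2
  p_C <- E * (ct$E_G * s_acc * ct$v * L2 + p_S) / (ct$kap * E + ct$E_G * L3)
  p_G <- ct$kap * p_C - p_S
  p_J <- ct$k_J * (if (stage == 4L) ct$E_Hp else EH)
  p_R <- (1 - ct$kap) * p_C - p_J
  dE  <- p_A - p_C
  dL  <- p_G / (3 * ct$E_G * L2)
  dEH <- if (stage < 4L) p_R else 0
  dER <- if (stage == 4L) p_R else 0
  # aging: damage-inducing compounds q, hazard h
  r  <- 3 * dL / L
  e  <- E / (L3 * ct$E_m)
  dq <- (q * (L3 / ct$L_m3) * ct$s_G + ct$h_a) * e * (s_acc * ct$v / L - r) - r * q
  dh <- q - r * h
  h_thin <- if (ct$thinning && stage >= 2L) {
    # keeps cohort feeding constant from birth on: feeding ~ s_acc * L^2
    (if (stage == 2L) 3 else 2) * max(dL, 0) / L
  } else 0
  dH <- (if (ct$aging) h else 0) + ct$h_B + h_thin
  list(c(dE, dL, dEH, dER, dq, dh, dH))
}

#' Hazard configuration for survival along a trajectory
#'
#' @param aging include the Weibull-Gompertz aging hazard (default TRUE).
#' @param background constant background hazard, 1/d (default 0).
#' @param thinning age-dependent thinning hazard that keeps the total feeding
#'   rate of a cohort constant: numbers decline as individual intake rises
#'   with (accelerated) squared length (default FALSE).
#' @return named list of class \code{hazard_config}.
#' @export
hazard_config <- function(aging = TRUE, background = 0, thinning = FALSE) {
  stopifnot(is.numeric(background), length(background) == 1, background >= 0)
  structure(list(aging = isTRUE(aging), background = background,
                 thinning = isTRUE(thinning)),
            class = "hazard_config")
}

#' Energy fluxes (powers) of a DEB state
#'
#' Computes the assimilation, mobilization, maintenance, growth, maturation
#' and dissipation fluxes at one or more states.  Mobilization follows the
#' algebraic closed form
#' \deqn{p_C = E (E_G s v L^2 + p_S) / (\kappa E + E_G L^3)}
#' with \eqn{s} the acceleration factor, so the same expression serves
#' embryos, juveniles and adults.  The kappa-rule identities
#' \eqn{\kappa p_C = p_S + p_G} and \eqn{(1-\kappa) p_C = p_J + p_R} hold by
#' construction; assimilation is zero before birth (feeding has not started).
#'
#' @param p a \code{\link{deb_params}} object.
#' @param E reserve, J (vectorized).
#' @param L structural length, cm (vectorized).
#' @param E_H cumulated maturity, J (vectorized).
#' @param f scaled functional response (default \code{p$f}).
#' @param s_acc acceleration factor \eqn{s_M = \min(L, L_j)/L_b}; 1 for std.
#' @param allow_negative_growth if FALSE (default), a negative growth flux
#'   (starvation / shrinking, out of scope at constant food) raises an error.
#' @return data.frame with columns \code{p_A}, \code{p_C}, \code{p_S},
#'   \code{p_G}, \code{p_J}, \code{p_R}, \code{p_D} (all J/d).
#' @export
#' @examples
#' p <- reference_params()
#' deb_powers(p, E = 1125 * 0.5^3, L = 0.5, E_H = p$E_Hp)
deb_powers <- function(p, E, L, E_H, f = p$f, s_acc = 1,
                       allow_negative_growth = FALSE) {
  validate_deb_params(p)
  stopifnot(f >= 0, f <= 1, all(s_acc >= 1))
  n <- max(length(E), length(L), length(E_H))
  E <- rep_len(E, n); L <- rep_len(L, n); E_H <- rep_len(E_H, n)
  s_acc <- rep_len(s_acc, n)
  L2 <- L^2; L3 <- L^3
  p_A <- ifelse(E_H >= p$E_Hb, f * p$p_Am * s_acc * L2, 0)
  p_S <- p$p_M * L3 + p$p_T * L2
  p_C <- E * (p$E_G * s_acc * p$v * L2 + p_S) / (p$kap * E + p$E_G * L3)
  p_G <- p$kap * p_C - p_S
  p_J <- p$k_J * pmin(E_H, p$E_Hp)
  p_R <- (1 - p$kap) * p_C - p_J
  adult <- E_H >= p$E_Hp
  p_D <- p_S + p_J + ifelse(adult, (1 - p$kap_R) * p_R, p_R)
  if (!allow_negative_growth && any(p_G < -1e-12 * pmax(p_S, 1e-300)))
    stop("negative growth flux (starvation/shrinking): not supported at constant food",
         call. = FALSE)
  data.frame(p_A = p_A, p_C = p_C, p_S = p_S, p_G = p_G,
             p_J = p_J, p_R = p_R, p_D = p_D)
}

# integrate one life stage with lsodar; terminates on maturity threshold
# (root 1), maturation stall (root 2) or cumulated-hazard stop (root 3).
# Returns list(out = deSolve matrix, iroot = which root (0 if none)).
.integrate_stage <- function(y0, t0, ct, threshold = NA_real_, horizon,
                             n_out = 2, H_stop = Inf,
                             rtol = 1e-8, atol = 1e-10) {
  rootfun <- function(a, y, ct) {
    r1 <- if (is.na(threshold)) 1 else y[3] - threshold
    # maturation stall: p_R crosses zero before the threshold is reached
    E <- y[1]; L <- y[2]
    L3 <- L^3
    s_acc <- if (ct$stage == 1L) 1 else if (ct$stage == 2L) L / ct$L_b else ct$s_M
    p_S <- ct$p_M * L3 + ct$p_T * L^2
    p_C <- E * (ct$E_G * s_acc * ct$v * L^2 + p_S) / (ct$kap * E + ct$E_G * L3)
    r2 <- if (is.na(threshold)) 1 else (1 - ct$kap) * p_C - ct$k_J * y[3]
    r3 <- if (is.finite(H_stop)) y[7] - H_stop else 1
    c(r1, r2, r3)
  }
  times <- if (n_out <= 2) c(t0, t0 + horizon)
           else seq(t0, t0 + horizon, length.out = n_out)
  out <- deSolve::lsodar(y = y0, times = times, func = .deb_rhs, parms = ct,
                         rootfunc = rootfun, rtol = rtol, atol = atol,
                         maxsteps = 1e5)
  iroot <- attr(out, "iroot")
  if (is.null(iroot)) iroot <- c(0L, 0L, 0L)
  list(out = out, iroot = iroot, troot = attr(out, "troot"))
}

# integrate one stage and, when a root terminated it, re-integrate densely up
# to the root so the output grid resolves the stage regardless of its length
.run_stage <- function(y0, t0, ct, threshold, horizon, n_out, H_stop,
                       rtol, atol) {
  probe <- .integrate_stage(y0, t0, ct, threshold = threshold,
                            horizon = horizon, n_out = 2, H_stop = H_stop,
                            rtol = rtol, atol = atol)
  t_end <- probe$out[nrow(probe$out), 1]
  if (n_out <= 2 || t_end <= t0 + 1e-12)
    return(list(out = probe$out, iroot = probe$iroot))
  dense <- .integrate_stage(y0, t0, ct, threshold = NA_real_,
                            horizon = t_end - t0, n_out = n_out,
                            H_stop = Inf, rtol = rtol, atol = atol)
  list(out = dense$out, iroot = probe$iroot)
}

#' Initial reserve of an egg (maternal effect)
#'
#' Finds the initial reserve \eqn{E_0} such that the scaled reserve density
#' at birth equals the scaled functional response \eqn{f} of the mother: the
#' maternal effect.  The embryo equations are integrated from a vanishingly
#' small structure seed and \eqn{E_0} is located by monotone bracketing and
#' root refinement on \eqn{e(a_b) - f}.
#'
#' @param p a \code{\link{deb_params}} object.
#' @param f scaled functional response of the mother (default \code{p$f}).
#' @param L_seed structural length seed, cm; small enough that results are
#'   insensitive to it (default 1e-4).
#' @param tol tolerance on the scaled reserve density at birth (default 1e-6).
#' @return list with \code{E_0} (J), and the by-products \code{a_b} (d),
#'   \code{L_b} (cm), \code{e_b} (scaled reserve density at birth).
#' @export
initial_reserve <- function(p, f = p$f, L_seed = 1e-4, tol = 1e-6) {
  validate_deb_params(p)
  stopifnot(f > 0, f <= 1)
  cmp <- compound_parameters(p)
  hz <- hazard_config(aging = FALSE)
  ct <- .deb_ct(p, f, hz, stage = 1L)
  cap <- 50 / cmp$k_M + 200 / (p$k_J + cmp$k_M)   # generous embryo horizon

  # near L = 0 structure grows linearly at rate v/3, so starting the clock at
  # 3 L_seed / v makes the reported a_b (nearly) seed-independent
  a0 <- 3 * L_seed / p$v
  birth <- function(E_0) {
    y0 <- c(E = E_0, L = L_seed, E_H = 0, E_R = 0, q = 0, h = 0, H = 0)
    st <- .integrate_stage(y0, a0, ct, threshold = p$E_Hb, horizon = cap)
    if (st$iroot[1] == 1L) {
      last <- st$out[nrow(st$out), ]
      list(ok = TRUE, a_b = unname(last[1]), E_b = unname(last[2]),
           L_b = unname(last[3]),
           e_b = unname(last[2] / (last[3]^3 * cmp$E_m)))
    } else list(ok = FALSE)
  }

  # bracket E_0: e(a_b) is increasing in E_0; stalls count as "too low"
  lo <- p$E_Hb / (1 - p$kap)
  hi <- lo
  f_hi <- NA_real_
  for (i in 1:80) {
    hi <- hi * 2
    b <- birth(hi)
    if (b$ok && b$e_b >= f) { f_hi <- b$e_b; break }
  }
  if (is.na(f_hi))
    stop(sprintf("unreachable birth for '%s': maturation stalls below E_Hb",
                 p$species_id), call. = FALSE)
  lo_ok <- FALSE
  for (i in 1:80) {
    b <- birth(lo)
    if (!b$ok || b$e_b < f) { lo_ok <- TRUE; break }
    hi <- lo; lo <- lo / 2
  }
  if (!lo_ok) stop("could not bracket initial reserve from below", call. = FALSE)

  g <- function(E_0) { b <- birth(E_0); if (!b$ok) -f else b$e_b - f }
  root <- stats::uniroot(g, lower = lo, upper = hi, tol = hi * 1e-12,
                         f.lower = -f, f.upper = f_hi - f)
  E_0 <- root$root
  b <- birth(E_0)
  if (!b$ok || abs(b$e_b - f) > tol)
    stop(sprintf("unreachable birth for '%s': no initial reserve yields reserve density %g at birth (viability boundary)",
                 p$species_id, f), call. = FALSE)
  list(E_0 = E_0, a_b = b$a_b, L_b = b$L_b, e_b = b$e_b)
}

#' Simulate a DEB life cycle
#'
#' Integrates the std or abj model at constant scaled functional response
#' from egg to \code{horizon}, with event-accurate detection of birth,
#' metamorphosis (abj) and puberty on the maturity thresholds.  The aging
#' module (and optional background and thinning hazards) yields the survival
#' probability along the trajectory.
#'
#' @param p a \code{\link{deb_params}} object.
#' @param f scaled functional response (default \code{p$f}).
#' @param horizon integration horizon, d.  Default runs to 25 von Bertalanffy
#'   time constants past birth, i.e. essentially to ultimate size.
#' @param E_0 initial reserve, J; computed by \code{\link{initial_reserve}}
#'   when NULL.
#' @param hazard a \code{\link{hazard_config}}.
#' @param until_S stop the adult stage once survival drops below this value
#'   (NULL to run to \code{horizon}).
#' @param n_out approximate number of output points per life stage.
#' @param L_seed embryo structure seed, cm.
#' @param end \code{"horizon"} (default), \code{"puberty"} or
#'   \code{"metamorphosis"} to stop at that event (later stages are not
#'   integrated).
#' @param rtol,atol solver tolerances.
#' @return object of class \code{deb_trajectory}: list with \code{states}
#'   (data.frame: a, E, L, E_H, E_R, q, h, S, s_acc, stage and the powers
#'   p_A..p_D), \code{events} (data.frame: event, a, L, E, W_w), \code{E_0},
#'   \code{params}, \code{f}, \code{hazard}.
#' @export
deb_simulate <- function(p, f = p$f, horizon = NULL, E_0 = NULL,
                         hazard = hazard_config(), until_S = NULL,
                         n_out = 300, L_seed = 1e-4,
                         end = c("horizon", "puberty", "metamorphosis"),
                         rtol = 1e-8, atol = 1e-10) {
  validate_deb_params(p)
  end <- match.arg(end)
  cmp <- compound_parameters(p)
  r_B <- cmp$k_M * cmp$g / (3 * (f + cmp$g))
  if (is.null(horizon)) horizon <- if (end != "horizon") 200 / r_B else 25 / r_B
  if (is.null(E_0)) {
    ir <- initial_reserve(p, f, L_seed = L_seed)
    E_0 <- ir$E_0
  }
  accel <- p$model == "abj" && p$E_Hj > p$E_Hb
  H_stop <- if (is.null(until_S)) Inf else -log(until_S)

  y <- c(E = E_0, L = L_seed, E_H = 0, E_R = 0, q = 0, h = 0, H = 0)
  t <- 3 * L_seed / p$v   # startup correction: structure grows at v/3 near L = 0
  segs <- list(); events <- list()
  L_b <- NA_real_; s_M <- 1
  # stage plan: (stage code, terminating threshold)
  plan <- list(c(1L, p$E_Hb))
  if (accel) plan <- c(plan, list(c(2L, p$E_Hj)))
  if (end != "metamorphosis") plan <- c(plan, list(c(3L, p$E_Hp)))
  if (end == "horizon") plan <- c(plan, list(c(4L, NA_real_)))
  ev_names <- c("birth", if (accel) "metamorphosis", "puberty")
  ev_i <- 0L

  for (k in seq_along(plan)) {
    stage <- as.integer(plan[[k]][1]); thr <- plan[[k]][2]
    if (!is.na(thr) && y[["E_H"]] >= thr) { # threshold already met (e.g. E_Hj=E_Hb)
      ev_i <- ev_i + 1L
      events[[length(events) + 1L]] <-
        .event_row(ev_names[ev_i], t, y, p)
      if (stage == 1L) L_b <- y[["L"]]
      if (stage == 2L) s_M <- y[["L"]] / L_b
      next
    }
    ct <- .deb_ct(p, f, hazard, stage, L_b = L_b, s_M = s_M)
    remaining <- horizon - t
    if (remaining <= 0) break
    st <- .run_stage(y, t, ct, threshold = thr, horizon = remaining,
                     n_out = n_out,
                     H_stop = if (stage == 4L) H_stop else Inf,
                     rtol = rtol, atol = atol)
    out <- st$out
    segs[[length(segs) + 1L]] <- cbind(out[, 1:8, drop = FALSE], stage = stage)
    last <- out[nrow(out), ]
    y <- last[2:8]; names(y) <- c("E", "L", "E_H", "E_R", "q", "h", "H")
    t <- last[[1]]
    hit <- st$iroot[1] == 1L
    if (!is.na(thr)) {
      if (!hit) {
        if (st$iroot[2] == 1L)
          stop(sprintf("unreachable %s for '%s': maturation stalls at E_H = %.4g J",
                       ev_names[ev_i + 1L], p$species_id, y[["E_H"]]),
               call. = FALSE)
        warning(sprintf("horizon %.4g d reached before %s", horizon,
                        ev_names[ev_i + 1L]))
        break
      }
      y[["E_H"]] <- thr   # re-initialize exactly at the event
      ev_i <- ev_i + 1L
      events[[length(events) + 1L]] <- .event_row(ev_names[ev_i], t, y, p)
      if (stage == 1L) L_b <- y[["L"]]
      if (stage == 2L) s_M <- y[["L"]] / L_b
    }
  }

  states <- as.data.frame(do.call(rbind, segs))
  names(states) <- c("a", "E", "L", "E_H", "E_R", "q", "h", "H", "stage")
  states <- states[!duplicated(states$a), , drop = FALSE]
  rownames(states) <- NULL
  states$E_H <- pmin(states$E_H, p$E_Hp)   # clamp solver-tolerance overshoot
  states$S <- exp(-states$H)
  states$H <- NULL
  states$s_acc <- ifelse(states$stage == 1, 1,
                    ifelse(states$stage == 2, states$L / L_b, s_M))
  pw <- deb_powers(p, states$E, states$L, states$E_H, f = f,
                   s_acc = states$s_acc, allow_negative_growth = TRUE)
  pw$p_A[states$stage == 1] <- 0
  states <- cbind(states, pw)
  ev <- do.call(rbind, events)
  traj <- list(states = states,
               events = ev,
               E_0 = E_0, L_b = L_b, s_M = s_M,
               params = p, f = f, hazard = hazard)
  class(traj) <- "deb_trajectory"
  traj
}

.event_row <- function(name, a, y, p) {
  data.frame(event = name, a = a, L = unname(y[["L"]]), E = unname(y[["E"]]),
             E_H = unname(y[["E_H"]]),
             W_w = wet_weight(p, unname(y[["L"]]),
                              unname(y[["E"]]) + unname(y[["E_R"]])),
             stringsAsFactors = FALSE)
}

#' Wet weight from structure and reserve
#'
#' \eqn{W_w = d_{Vw} L^3 + (E + E_R) w_E / (\mu_E \, dwr)}: wet structure
#' plus reserve (and reproduction buffer) converted to wet mass through the
#' composition conventions.
#'
#' @param p a \code{\link{deb_params}} object.
#' @param L structural length, cm.
#' @param E_tot reserve plus reproduction buffer, J.
#' @return wet weight, g.
#' @export
wet_weight <- function(p, L, E_tot) {
  cc <- p$composition
  cc$d_Vw * L^3 + E_tot * cc$w_E / (cc$mu_E * cc$dwr)
}

#' @export
print.deb_trajectory <- function(x, ...) {
  cat(sprintf("DEB trajectory [%s] for '%s', f = %g, E_0 = %.6g J\n",
              x$params$model, x$params$species_id, x$f, x$E_0))
  cat(sprintf("  %d states over %.4g d; final L = %.4g cm, S = %.3g\n",
              nrow(x$states), max(x$states$a),
              x$states$L[nrow(x$states)], x$states$S[nrow(x$states)]))
  if (!is.null(x$events)) {
    cat("  events:\n")
    print(x$events, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a DEB trajectory
#'
#' @param x a \code{deb_trajectory}.
#' @param which subset of \code{c("L", "E", "E_H", "S")}.
#' @param ... passed to \code{plot}.
#' @export
plot.deb_trajectory <- function(x, which = c("L", "E", "E_H", "S"), ...) {
  st <- x$states
  which <- match.arg(which, several.ok = TRUE)
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  labs <- c(L = "structural length, cm", E = "reserve, J",
            E_H = "maturity, J", S = "survival")
  for (v in which) {
    graphics::plot(st$a, st[[v]], type = "l", xlab = "age, d",
                   ylab = labs[[v]], ...)
    if (!is.null(x$events))
      graphics::abline(v = x$events$a, lty = 3, col = "grey40")
  }
  invisible(x)
}
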