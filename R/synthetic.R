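# Synthetic parameter tables with the co-variation structure the comparative
# layer assumes: log-spread body-size scaling of extensive parameters, a
# waste-to-hurry subgroup with jointly elevated specific assimilation and
# somatic maintenance, an accelerating subgroup, and a demand-like subgroup
# with large neonates, high supply stress and low allocation to soma.

#' Configuration of the synthetic parameter generator
#'
#' @param n_per_group species per group.
#' @param groups subset of \code{"baseline"}, \code{"waste_to_hurry"},
#'   \code{"accelerating"}, \code{"demand"}.
#' @param zoom_range range of the zoom factor z (log-uniform); z equals the
#'   maximum structural length in cm of the drawn species before scatter.
#' @param scatter_sd lognormal scatter of parameters, log10 units.
#' @param wth_meanlog,wth_sdlog natural-log mean and sd of the shared
#'   waste-to-hurry multiplier applied to both specific assimilation and
#'   specific somatic maintenance (defaults: median 3, mild spread).
#' @param s_M_range target range of the realized acceleration factor in the
#'   accelerating group.
#' @param demand list of demand-group adjustments: multipliers on the
#'   reference \code{E_Hb} and \code{E_Hp} (beyond the z^3 scaling), on
#'   \code{k_J}, and the allocation fraction \code{kap}.
#' @param seed integer seed fixing the full table.
#' @param reference the anchor parameter set (default
#'   \code{\link{reference_params}}).
#' @return named list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_per_group = 50,
                             groups = c("baseline", "waste_to_hurry",
                                        "accelerating", "demand"),
                             zoom_range = c(0.2, 20),
                             scatter_sd = 0.05,
                             wth_meanlog = log(3), wth_sdlog = 0.2,
                             s_M_range = c(2, 6),
                             demand = list(E_Hb_mult = 300, E_Hp_mult = 10,
                                           k_J_mult = 3, kap = 0.55),
                             seed = 1,
                             reference = reference_params()) {
  groups <- match.arg(groups, several.ok = TRUE)
  stopifnot(n_per_group >= 1, scatter_sd >= 0,
            zoom_range[1] > 0, zoom_range[2] >= zoom_range[1],
            s_M_range[1] >= 1, s_M_range[2] >= s_M_range[1])
  structure(list(n_per_group = n_per_group, groups = groups,
                 zoom_range = zoom_range, scatter_sd = scatter_sd,
                 wth_meanlog = wth_meanlog, wth_sdlog = wth_sdlog,
                 s_M_range = s_M_range, demand = demand, seed = seed,
                 reference = reference,
                 scatter_family = "lognormal"),
            class = "synthetic_config")
}

# calibrate E_Hj so the realized acceleration factor matches the target;
# secant iteration on log E_Hj starting from the cube-law guess
.calibrate_E_Hj <- function(p, s_M_target, E_0, tol = 0.02, maxit = 8) {
  realized <- function(E_Hj) {
    pj <- p; pj$E_Hj <- E_Hj
    tr <- deb_simulate(pj, E_0 = E_0, end = "metamorphosis", n_out = 2)
    tr$s_M
  }
  x1 <- log(p$E_Hb * s_M_target^3)
  s1 <- realized(exp(x1))
  if (abs(s1 - s_M_target) <= tol * s_M_target) return(exp(x1))
  x2 <- x1 + 3 * (log(s_M_target) - log(s1))
  for (i in seq_len(maxit)) {
    x2 <- min(x2, log(p$E_Hp * 0.99))
    s2 <- realized(exp(x2))
    if (abs(s2 - s_M_target) <= tol * s_M_target) return(exp(x2))
    slope <- (x2 - x1) / (log(s2) - log(s1))
    x1 <- x2; s1 <- s2
    x2 <- x2 + slope * (log(s_M_target) - log(s2))
  }
  exp(x2)
}

#' Generate a synthetic table of DEB parameters
#'
#' Per species: a zoom factor z is drawn log-uniformly; the extensive
#' parameter \eqn{\{p_{Am}\}} is set to \eqn{z [p_M]_{ref}/\kappa_{ref}} (so
#' z is the maximum structural length before scatter) and the maturity
#' thresholds scale with \eqn{z^3}; intensive parameters stay at their
#' reference values.  All parameters receive independent lognormal scatter.
#' The waste-to-hurry group multiplies both \eqn{\{p_{Am}\}} and
#' \eqn{[p_M]} by a shared lognormal factor (no direct edit of lifespan:
#' any lifespan response must emerge from the mechanism).  The accelerating
#' group uses the abj model with \eqn{E_H^j} calibrated so the realized
#' acceleration factor lands in the configured range.  The demand group
#' raises the maturity thresholds and maturity maintenance and lowers
#' \eqn{\kappa}.  Draws failing the analytic viability screen (positive
#' reproduction flux at ultimate size, \eqn{E_H^b < E_H^p}) are resampled,
#' up to 100 times per row.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of \code{\link{deb_params}} (class \code{deb_params_set})
#'   with attribute \code{design}: data.frame of species_id, group, z and the
#'   waste-to-hurry multiplier / target s_M where applicable.
#' @export
generate_params <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  ref <- config$reference
  sd10 <- config$scatter_sd
  jitter10 <- function(x) x * 10^stats::rnorm(1, 0, sd10)
  out <- list(); design <- list()
  i <- 0L
  for (grp in config$groups) {
    for (j in seq_len(config$n_per_group)) {
      i <- i + 1L
      id <- sprintf("%s_%03d", grp, j)
      for (attempt in 1:100) {
        z <- exp(stats::runif(1, log(config$zoom_range[1]),
                              log(config$zoom_range[2])))
        kap_base <- if (grp == "demand") config$demand$kap else ref$kap
        kap <- stats::plogis(stats::qlogis(kap_base) +
                               stats::rnorm(1, 0, sd10 * log(10)))
        p_M <- jitter10(ref$p_M)
        v <- jitter10(ref$v)
        k_J <- jitter10(ref$k_J *
                          if (grp == "demand") config$demand$k_J_mult else 1)
        E_G <- jitter10(ref$E_G)
        p_Am <- jitter10(z * ref$p_M / ref$kap)
        E_Hb <- jitter10(ref$E_Hb * z^3 *
                           if (grp == "demand") config$demand$E_Hb_mult else 1)
        E_Hp <- jitter10(ref$E_Hp * z^3 *
                           if (grp == "demand") config$demand$E_Hp_mult else 1)
        h_a <- jitter10(ref$h_a)
        mult <- NA_real_; s_M_target <- NA_real_
        if (grp == "waste_to_hurry") {
          mult <- stats::rlnorm(1, config$wth_meanlog, config$wth_sdlog)
          p_Am <- p_Am * mult
          p_M <- p_M * mult
        }
        # analytic viability screen at f = 1
        L_inf <- kap * p_Am / p_M
        ok <- E_Hb < 0.9 * E_Hp &&
          (1 - kap) * p_Am * L_inf^2 > 1.05 * k_J * E_Hp
        if (!ok) next
        model <- if (grp == "accelerating") "abj" else "std"
        p <- deb_params(species_id = id, taxon = grp, model = model,
                        p_Am = p_Am, v = v, kap = kap, kap_R = ref$kap_R,
                        p_M = p_M, p_T = ref$p_T, k_J = k_J, E_G = E_G,
                        E_Hb = E_Hb, E_Hj = E_Hb, E_Hp = E_Hp,
                        h_a = h_a, s_G = ref$s_G, T_A = ref$T_A,
                        T_ref = ref$T_ref)
        if (grp == "accelerating") {
          s_M_target <- exp(stats::runif(1, log(config$s_M_range[1]),
                                         log(config$s_M_range[2])))
          E_0 <- initial_reserve(p)$E_0
          E_Hj <- try(.calibrate_E_Hj(p, s_M_target, E_0), silent = TRUE)
          if (inherits(E_Hj, "try-error") || E_Hj >= E_Hp) next
          p$E_Hj <- E_Hj
          validate_deb_params(p)
        }
        out[[i]] <- p
        design[[i]] <- data.frame(species_id = id, group = grp, z = z,
                                  wth_multiplier = mult,
                                  s_M_target = s_M_target,
                                  resamples = attempt - 1L,
                                  stringsAsFactors = FALSE)
        break
      }
      if (length(out) < i)
        stop(sprintf("row %s: no viable draw in 100 resamples; revisit config",
                     id), call. = FALSE)
    }
  }
  attr(out, "design") <- do.call(rbind, design)
  attr(out, "config") <- config
  class(out) <- "deb_params_set"
  out
}

#' Designed effects behind a synthetic table
#'
#' Returns the ground truth a recovery test can assert: the group of every
#' row, the zoom factors, the waste-to-hurry multipliers (median equal to
#' \code{exp(wth_meanlog)}), the target acceleration range, and the expected
#' unit slope of log maximum reserve capacity on log specific assimilation in
#' the baseline group.
#'
#' @param x a \code{deb_params_set} from \code{\link{generate_params}}, or a
#'   \code{\link{synthetic_config}} (regenerates the design).
#' @return list with \code{design} (per-row data.frame),
#'   \code{wth_multiplier_median}, \code{s_M_range},
#'   \code{expected_Em_pAm_slope}.
#' @export
ground_truth <- function(x) {
  if (inherits(x, "synthetic_config")) x <- generate_params(x)
  stopifnot(inherits(x, "deb_params_set"))
  cfg <- attr(x, "config")
  list(design = attr(x, "design"),
       wth_multiplier_median = exp(cfg$wth_meanlog),
       s_M_range = cfg$s_M_range,
       expected_Em_pAm_slope = 1)
}

#' @export
print.deb_params_set <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("synthetic DEB parameter set: %d species\n", length(x)))
  print(table(d$group))
  invisible(x)
}
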