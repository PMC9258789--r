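#' Primary parameters of a Dynamic Energy Budget model
#'
#' Constructs and validates the primary parameter set of a std or abj DEB
#' model for one species.  All rates are expressed at the reference
#' temperature \code{T_ref}; energies in J, lengths in cm (volumetric
#' structural length, structure volume \eqn{V = L^3}), times in days.
#'
#' The std model covers three life stages (embryo, juvenile, adult) with
#' isomorphic growth throughout.  The abj model inserts a metabolic
#' acceleration phase between birth (maturity \code{E_Hb}) and metamorphosis
#' (\code{E_Hj}) during which specific assimilation and energy conductance
#' increase proportionally to structural length (V1-morphic growth).  Setting
#' \code{E_Hj = E_Hb} recovers the std model exactly.
#'
#' @param species_id character label for the species.
#' @param taxon character taxon label used by the comparative layer.
#' @param model \code{"std"} or \code{"abj"}.
#' @param p_Am maximum surface-area-specific assimilation rate, J/d/cm^2.
#' @param v energy conductance, cm/d.
#' @param kap allocation fraction to soma, in (0,1).
#' @param kap_R reproduction efficiency, in (0,1].
#' @param p_M volume-specific somatic maintenance rate, J/d/cm^3.
#' @param p_T surface-area-specific somatic maintenance rate, J/d/cm^2.
#'   Default 0; cases allowing its estimation are rare.
#' @param k_J maturity maintenance rate coefficient, 1/d.
#' @param E_G volume-specific cost of structure, J/cm^3.
#' @param E_Hb maturity at birth, J (feeding starts when maturity reaches it).
#' @param E_Hj maturity at metamorphosis, J; required for abj (defaults to
#'   \code{E_Hb}, i.e. no acceleration).
#' @param E_Hp maturity at puberty, J (allocation to reproduction starts).
#' @param h_a Weibull aging acceleration, 1/d^2.
#' @param s_G Gompertz stress coefficient, dimensionless.  Near zero gives
#'   Weibull-type survival; 1 gives abrupt ("programmed") death near the mean
#'   age at death.
#' @param T_A Arrhenius temperature, K.
#' @param T_ref reference temperature, K (default 293.15 K = 20 C).
#' @param T_body typical body temperature, K (default \code{T_ref}).
#' @param f scaled functional response in [0,1] (default 1, food ad libitum).
#' @param composition list of composition conventions used for weights and
#'   respiration; see \code{\link{deb_composition}}.
#'
#' @return An object of class \code{deb_params} (a named list).
#' @seealso \code{\link{compound_parameters}}, \code{\link{reference_params}},
#'   \code{\link{deb_simulate}}, \code{\link{trait_record}}
#' @export
#' @examples
#' p <- reference_params()
#' compound_parameters(p)
deb_params <- function(species_id = "sp", taxon = "none", model = c("std", "abj"),
                       p_Am, v, kap, kap_R = 0.95, p_M, p_T = 0, k_J, E_G,
                       E_Hb, E_Hj = NULL, E_Hp, h_a, s_G = 1e-4,
                       T_A = 8000, T_ref = 293.15, T_body = T_ref, f = 1,
                       composition = deb_composition()) {
  model <- match.arg(model)
  if (is.null(E_Hj) || (length(E_Hj) == 1 && is.na(E_Hj))) E_Hj <- E_Hb
  p <- list(species_id = as.character(species_id), taxon = as.character(taxon),
            model = model,
            p_Am = p_Am, v = v, kap = kap, kap_R = kap_R, p_M = p_M, p_T = p_T,
            k_J = k_J, E_G = E_G, E_Hb = E_Hb, E_Hj = E_Hj, E_Hp = E_Hp,
            h_a = h_a, s_G = s_G, T_A = T_A, T_ref = T_ref, T_body = T_body,
            f = f, composition = composition)
  class(p) <- "deb_params"
  validate_deb_params(p)
  p
}

#' Composition and conversion conventions
#'
#' Constants used to convert energies to masses and to close the mass balance
#' for respiration.  These are conventions of the generalized animal, not
#' species observations: dry structure density \code{d_V}, molar weights and
#' chemical potentials of reserve and structure, chemical indices (H, O, N per
#' C) of food, structure, reserve and faeces, digestion efficiency
#' \code{kap_X} and faeces yield \code{y_PX}, wet structure density
#' \code{d_Vw} and reserve dry-to-wet fraction \code{dwr} used for wet weight.
#'
#' @param d_V dry structure density, g/cm^3.
#' @param w_E,w_V molar weights of reserve and structure, g/C-mol.
#' @param mu_E,mu_V chemical potentials of reserve and structure, J/C-mol.
#' @param n_E,n_V,n_X,n_P chemical indices c(C, H, O, N) per C-atom.
#' @param mu_X chemical potential of food, J/C-mol.
#' @param kap_X digestion (assimilation) efficiency of food to reserve.
#' @param y_PX faeces yield, C-mol faeces per C-mol food.
#' @param d_Vw wet structure density, g/cm^3.
#' @param dwr reserve dry-to-wet weight ratio.
#' @return named list of class \code{deb_composition}.
#' @export
deb_composition <- function(d_V = 0.1, w_E = 23.9, w_V = 23.9,
                            mu_E = 550000, mu_V = 500000,
                            n_E = c(1, 1.8, 0.5, 0.15),
                            n_V = c(1, 1.8, 0.5, 0.15),
                            n_X = c(1, 1.8, 0.5, 0.15),
                            n_P = c(1, 1.8, 0.5, 0.15),
                            mu_X = 525000, kap_X = 0.8, y_PX = 0.1,
                            d_Vw = 1, dwr = 0.2) {
  structure(list(d_V = d_V, w_E = w_E, w_V = w_V, mu_E = mu_E, mu_V = mu_V,
                 n_E = n_E, n_V = n_V, n_X = n_X, n_P = n_P,
                 mu_X = mu_X, kap_X = kap_X, y_PX = y_PX,
                 d_Vw = d_Vw, dwr = dwr),
            class = "deb_composition")
}

validate_deb_params <- function(p) {
  stop_field <- function(field, why)
    stop(sprintf("invalid deb_params for '%s': field '%s' %s",
                 p$species_id, field, why), call. = FALSE)
  pos <- c("p_Am", "v", "p_M", "E_G", "E_Hb", "E_Hp", "h_a", "k_J",
           "T_A", "T_ref", "T_body")
  for (fld in pos) {
    x <- p[[fld]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
      stop_field(fld, "must be a single positive finite number")
  }
  nonneg <- c("p_T", "s_G", "E_Hj")
  for (fld in nonneg) {
    x <- p[[fld]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
      stop_field(fld, "must be a single non-negative finite number")
  }
  if (!is.finite(p$kap) || p$kap <= 0 || p$kap >= 1)
    stop_field("kap", "must lie strictly in (0, 1)")
  if (!is.finite(p$kap_R) || p$kap_R <= 0 || p$kap_R > 1)
    stop_field("kap_R", "must lie in (0, 1]")
  if (!is.finite(p$f) || p$f < 0 || p$f > 1)
    stop_field("f", "must lie in [0, 1]")
  if (p$E_Hb > p$E_Hj) stop_field("E_Hj", "must satisfy E_Hb <= E_Hj")
  if (p$E_Hj > p$E_Hp) stop_field("E_Hp", "must satisfy E_Hj <= E_Hp")
  if (p$model == "std" && p$E_Hj != p$E_Hb)
    stop_field("E_Hj", "must equal E_Hb for the std model")
  invisible(p)
}

#' Compound DEB parameters
#'
#' Derives the standard compound quantities from a primary parameter set:
#' maximum reserve density \eqn{[E_m] = \{p_{Am}\}/v}, maximum volumetric
#' length \eqn{L_m = \kappa \{p_{Am}\}/[p_M]}, energy investment ratio
#' \eqn{g = E_G/(\kappa [E_m])}, somatic maintenance rate coefficient
#' \eqn{k_M = [p_M]/E_G}, heating length \eqn{L_T = \{p_T\}/[p_M]} and the
#' reserve contribution to weight \eqn{\omega = [E_m] w_E / (d_V \mu_E)}.
#'
#' @param p a \code{\link{deb_params}} object.
#' @return named list with \code{E_m}, \code{L_m}, \code{g}, \code{k_M},
#'   \code{L_T}, \code{omega}.
#' @export
compound_parameters <- function(p) {
  validate_deb_params(p)
  E_m <- p$p_Am / p$v
  L_m <- p$kap * p$p_Am / p$p_M
  list(E_m = E_m,
       L_m = L_m,
       g   = p$E_G / (p$kap * E_m),
       k_M = p$p_M / p$E_G,
       L_T = p$p_T / p$p_M,
       omega = E_m * p$composition$w_E / (p$composition$d_V * p$composition$mu_E))
}

#' Reference parameter set (generalized animal)
#'
#' The conventional "generalized animal" parameter set with maximum
#' structural length 1 cm, used as the anchor of the synthetic generator and
#' as a fixture throughout the package.  Values are conventions of DEB
#' practice, not measurements of any species.
#'
#' @param ... fields passed on to \code{\link{deb_params}} to override
#'   defaults (e.g. \code{kap = 0.5}, \code{model = "abj"}).
#' @return a \code{\link{deb_params}} object.
#' @export
reference_params <- function(...) {
  args <- list(species_id = "generalized_animal", taxon = "reference",
               model = "std",
               p_Am = 22.5, v = 0.02, kap = 0.8, kap_R = 0.95,
               p_M = 18, p_T = 0, k_J = 0.002, E_G = 2800,
               E_Hb = 0.275, E_Hp = 166, h_a = 1e-6, s_G = 0.01,
               T_A = 8000, T_ref = 293.15)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(deb_params, args)
}

#' @export
print.deb_params <- function(x, ...) {
  cat(sprintf("DEB parameters [%s] for '%s' (taxon %s)\n",
              x$model, x$species_id, x$taxon))
  cmp <- compound_parameters(x)
  cat(sprintf("  p_Am = %g J/d.cm^2, v = %g cm/d, kap = %g, p_M = %g J/d.cm^3\n",
              x$p_Am, x$v, x$kap, x$p_M))
  cat(sprintf("  k_J = %g 1/d, E_G = %g J/cm^3, kap_R = %g, p_T = %g\n",
              x$k_J, x$E_G, x$kap_R, x$p_T))
  cat(sprintf("  E_Hb = %g, E_Hj = %g, E_Hp = %g J; h_a = %g 1/d^2, s_G = %g\n",
              x$E_Hb, x$E_Hj, x$E_Hp, x$h_a, x$s_G))
  cat(sprintf("  T_A = %g K (T_ref = %g K); f = %g\n", x$T_A, x$T_ref, x$f))
  cat(sprintf("  compound: E_m = %g J/cm^3, L_m = %g cm, g = %g, k_M = %g 1/d\n",
              cmp$E_m, cmp$L_m, cmp$g, cmp$k_M))
  invisible(x)
}

#' Arrhenius temperature correction
#'
#' Converts a physiological rate or a time from the reference temperature to
#' another body temperature with the one-parameter Arrhenius relation.  The
#' correction factor is \eqn{c_T = \exp(T_A/T_{ref} - T_A/T)}; rates are
#' multiplied by \eqn{c_T}, times divided by it.  Quantities of dimension
#' 1/time^2 (the Weibull aging acceleration) are corrected by \eqn{c_T^2}.
#'
#' @param x value(s) at \code{T_ref}.
#' @param kind one of \code{"rate"}, \code{"time"}, \code{"rate2"}
#'   (dimension 1/d^2).
#' @param T target temperature, K.
#' @param p a \code{deb_params} object supplying \code{T_A} and \code{T_ref},
#'   or NULL if \code{T_A}/\code{T_ref} given directly.
#' @param T_A,T_ref Arrhenius and reference temperature, K (defaults taken
#'   from \code{p}).
#' @return corrected value(s), same shape as \code{x}.
#' @export
#' @examples
#' temp_correct(1, "rate", T = 283.15, T_A = 8000, T_ref = 293.15)
temp_correct <- function(x, kind = c("rate", "time", "rate2"), T, p = NULL,
                         T_A = p$T_A, T_ref = p$T_ref) {
  kind <- match.arg(kind)
  stopifnot(is.finite(T), T > 0, is.finite(T_A), is.finite(T_ref))
  c_T <- exp(T_A / T_ref - T_A / T)
  switch(kind,
         rate  = x * c_T,
         time  = x / c_T,
         rate2 = x * c_T^2)
}
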