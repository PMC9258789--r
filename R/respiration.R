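# Respiration by mass balance over the organic fluxes.
#
# Dioxygen consumption is tied to the three aggregate chemical
# transformations of the budget: assimilation (food -> reserve + faeces),
# dissipation (reserve -> minerals) and growth (reserve -> structure).  For
# each, the organic C-mol fluxes per joule of the corresponding power are
# fixed by the composition conventions, and the mineral fluxes (CO2, H2O,
# O2, NH3) follow from closing the element balance:
#   n_O %*% J_org + n_M %*% J_min = 0  =>  J_min = -solve(n_M) %*% n_O %*% J_org
# The O2 rows give one coefficient eta (mol O2 per J) per power, so
#   J_O2 = eta_A p_A + eta_D p_D + eta_G p_G .

#' Oxygen coefficients from composition by mineral closure
#'
#' Solves the 4x4 element balance (C, H, O, N against CO2, H2O, O2, NH3) for
#' each of the assimilation, dissipation and growth transformations and
#' returns the mol-O2-per-joule coefficients.
#'
#' @param composition a \code{\link{deb_composition}} object.
#' @param E_G volume-specific cost of structure, J/cm^3 (sets how much
#'   reserve is fixed into structure per joule of growth flux).
#' @return named numeric vector \code{c(eta_A, eta_D, eta_G)}, mol O2 / J
#'   (consumption positive).
#' @export
respiration_coefficients <- function(composition = deb_composition(), E_G) {
  cc <- composition
  # mineral matrix: columns CO2, H2O, O2, NH3; rows C, H, O, N
  n_M <- matrix(c(1, 0, 2, 0,
                  0, 2, 1, 0,
                  0, 0, 2, 0,
                  0, 3, 0, 1), nrow = 4,
                dimnames = list(c("C", "H", "O", "N"),
                                c("CO2", "H2O", "O2", "NH3")))
  o2_of <- function(J_org, n_cols) {
    r <- n_cols %*% J_org                    # element production of organics
    J_min <- solve(n_M, -r)                  # minerals closing the balance
    -as.numeric(J_min["O2", 1])              # consumption positive
  }
  # assimilation, per J of p_A: food in, reserve + faeces out
  J_X <- 1 / (cc$kap_X * cc$mu_X)
  eta_A <- o2_of(c(-J_X, 1 / cc$mu_E, cc$y_PX * J_X),
                 cbind(cc$n_X, cc$n_E, cc$n_P))
  # dissipation, per J of p_D: reserve fully oxidized
  eta_D <- o2_of(-1 / cc$mu_E, cbind(cc$n_E))
  # growth, per J of p_G: reserve in, structure out, overhead oxidized
  eta_G <- o2_of(c(-1 / cc$mu_E, cc$d_V / (cc$w_V * E_G)),
                 cbind(cc$n_E, cc$n_V))
  eta <- c(eta_A = eta_A, eta_D = eta_D, eta_G = eta_G)
  if (any(eta < 0))
    stop("non-physical composition: negative oxygen coefficient", call. = FALSE)
  eta
}

#' Dioxygen consumption of a DEB state
#'
#' \eqn{J_{O2} = \eta_A p_A + \eta_D p_D + \eta_G p_G} with coefficients from
#' \code{\link{respiration_coefficients}}.  At constant scaled functional
#' response the result, viewed as a function of structural length, is a
#' polynomial with constant, squared and cubed length terms only.
#'
#' @inheritParams deb_powers
#' @return O2 consumption, mol/d (vectorized like the state arguments).
#' @export
#' @examples
#' p <- reference_params()
#' L <- 0.5
#' deb_respiration(p, E = (p$p_Am / p$v) * L^3, L = L, E_H = p$E_Hp)
deb_respiration <- function(p, E, L, E_H, f = p$f, s_acc = 1) {
  pw <- deb_powers(p, E, L, E_H, f = f, s_acc = s_acc,
                   allow_negative_growth = TRUE)
  eta <- respiration_coefficients(p$composition, p$E_G)
  unname(eta["eta_A"] * pw$p_A + eta["eta_D"] * pw$p_D + eta["eta_G"] * pw$p_G)
}
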