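#' Growth rates from division timing and volume asymmetry
#'
#' Yeast cells grow exponentially and divide when they reach a fixed
#' volume; the mother keeps a fraction `pi` of that volume and the bud
#' receives `1 - pi`. This ties the growth rates to the doubling times:
#' \eqn{e^{-\gamma_M T_M} = \pi} and \eqn{e^{-\gamma_D T_D} = 1 - \pi}.
#'
#' @param T_M Mother doubling time, hr.
#' @param T_D Daughter doubling time, hr.
#' @param pi Mother volume fraction at division, in (0, 1).
#'
#' @return Named numeric `c(gamma_M, gamma_D)` in 1/hr.
#' @examples
#' derive_rates(2, 3, 0.6) # ~0.26 and ~0.31 per hr
#' @export
derive_rates <- function(T_M, T_D, pi) {
  if (!(pi > 0 && pi < 1)) stop("'pi' must lie strictly between 0 and 1")
  if (!(T_M > 0 && T_D > 0)) stop("doubling times must be positive")
  c(gamma_M = -log(pi) / T_M, gamma_D = -log(1 - pi) / T_D)
}

#' Concentration jump coefficients at budding
#'
#' At division the mother retains mass fraction `pi + eps` of a species and
#' the daughter receives `1 - pi - eps`; dividing by the respective volume
#' fractions gives the concentration jumps
#' \eqn{\alpha_M = \epsilon/\pi}, \eqn{\alpha_D = -\epsilon/(1-\pi)}, so a
#' post-division concentration is `(1 + alpha) * C`. Volume-weighted mass
#' is conserved: \eqn{\pi(1+\alpha_M) + (1-\pi)(1+\alpha_D) = 1}.
#'
#' @param pi Mother volume fraction at division, in (0, 1).
#' @param eps Mass transmission bias, in the open interval `(-pi, 1 - pi)`;
#'   positive values bias retention towards the mother. The degenerate
#'   endpoints (all-or-none transmission) are excluded.
#'
#' @return Named numeric `c(alpha_M, alpha_D)`, dimensionless.
#' @examples
#' partition_coefficients(0.6, 0.1) # c(1/6, -1/4)
#' @export
partition_coefficients <- function(pi, eps) {
  if (!(pi > 0 && pi < 1)) stop("'pi' must lie strictly between 0 and 1")
  if (!(eps > -pi && eps < 1 - pi)) {
    stop(sprintf("'eps' must lie strictly in (-pi, 1-pi) = (%g, %g)", -pi, 1 - pi))
  }
  c(alpha_M = eps / pi, alpha_D = -eps / (1 - pi))
}

#' Budding-division parameters
#'
#' Geometry and timing of asymmetric budding division, with the derived
#' growth rates and per-species concentration jump coefficients. The
#' aggregate (`S`) and monomer (`V`) species carry separate transmission
#' biases: aggregate retention by the mother is well documented, whereas
#' soluble monomer diffuses fast and by default partitions with volume
#' (`eps_V = 0`).
#'
#' @inheritParams derive_rates
#' @param eps_S Aggregate mass transmission bias.
#' @param eps_V Monomer mass transmission bias.
#'
#' @return An object of class `division_params` with fields `T_M`, `T_D`,
#'   `pi`, `eps_S`, `eps_V` and derived `gamma_M`, `gamma_D`, `alpha_M_S`,
#'   `alpha_D_S`, `alpha_M_V`, `alpha_D_V`.
#' @examples
#' division_params() # Table-style defaults: T_M = 2, T_D = 3, pi = 0.6
#' @export
division_params <- function(T_M = 2, T_D = 3, pi = 0.6, eps_S = 0.1, eps_V = 0) {
  rates <- derive_rates(T_M, T_D, pi)
  a_S <- partition_coefficients(pi, eps_S)
  a_V <- partition_coefficients(pi, eps_V)
  structure(list(T_M = T_M, T_D = T_D, pi = pi, eps_S = eps_S, eps_V = eps_V,
                 gamma_M = rates[["gamma_M"]], gamma_D = rates[["gamma_D"]],
                 alpha_M_S = a_S[["alpha_M"]], alpha_D_S = a_S[["alpha_D"]],
                 alpha_M_V = a_V[["alpha_M"]], alpha_D_V = a_V[["alpha_D"]]),
            class = "division_params")
}

#' @export
print.division_params <- function(x, ...) {
  cat("Budding-division parameters:\n")
  cat(sprintf("  T_M = %g hr, T_D = %g hr, pi = %g\n", x$T_M, x$T_D, x$pi))
  cat(sprintf("  gamma_M = %.4f /hr, gamma_D = %.4f /hr\n", x$gamma_M, x$gamma_D))
  cat(sprintf("  eps_S = %g (alpha_M = %.4f, alpha_D = %.4f)\n",
              x$eps_S, x$alpha_M_S, x$alpha_D_S))
  cat(sprintf("  eps_V = %g (alpha_M = %.4f, alpha_D = %.4f)\n",
              x$eps_V, x$alpha_M_V, x$alpha_D_V))
  invisible(x)
}

#' Apply one division impulse to a cell state
#'
#' Splits one cell's concentrations into the post-division mother and
#' daughter states, multiplying each species by `1 + alpha` for the
#' corresponding side (right-limit convention: the returned values are the
#' states immediately after the impulse).
#'
#' @param state A [cell_state()] or numeric `(V, S)`: the dividing cell at
#'   the moment of division.
#' @param params A [division_params()] object.
#'
#' @return A list with `cell_state` elements `mother` and `daughter`.
#' @examples
#' apply_division(cell_state(2.5, 1), division_params())
#' @export
apply_division <- function(state, params) {
  st <- as_state(state)
  stopifnot(inherits(params, "division_params"))
  list(mother = cell_state((1 + params$alpha_M_V) * st[["V"]],
                           (1 + params$alpha_M_S) * st[["S"]]),
       daughter = cell_state((1 + params$alpha_D_V) * st[["V"]],
                             (1 + params$alpha_D_S) * st[["S"]]))
}
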