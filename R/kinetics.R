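#' Intracellular kinetic parameters
#'
#' Bundle the parameters of the bistable Sup35 aggregation kinetics: a
#' constant monomer supply, first-order dilution by cell growth, and a
#' cooperative (Hill-type) conversion of soluble monomer into the
#' aggregated prion conformation.
#'
#' @param lam Monomer basal production rate \eqn{\lambda}, uM/hr.
#' @param rho Maximal aggregate replication rate \eqn{\rho}, 1/hr.
#' @param K Replication efficiency threshold, uM.
#' @param n Replication efficiency (Hill) order, dimensionless. Bistability
#'   requires `n > 1`; smaller orders are accepted with a warning because
#'   they remain meaningful for the monostable regime.
#' @param gamma Growth/dilution rate \eqn{\gamma}, 1/hr. Typically one of
#'   the mother or daughter growth rates derived by [derive_rates()].
#'
#' @return An object of class `kinetic_params`.
#' @seealso [ode_rhs()], [find_equilibria()], [division_params()]
#' @examples
#' kp <- kinetic_params(lam = 0.7, rho = 10, K = 1, n = 5, gamma = 0.2554)
#' @export
kinetic_params <- function(lam = 0.7, rho = 10, K = 1, n = 5, gamma) {
  stopifnot(is.numeric(lam), length(lam) == 1L,
            is.numeric(rho), length(rho) == 1L,
            is.numeric(K), length(K) == 1L,
            is.numeric(n), length(n) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (!(lam > 0)) stop("'lam' must be positive")
  if (rho < 0) stop("'rho' must be nonnegative")
  if (!(K > 0)) stop("'K' must be positive")
  if (!(gamma > 0)) stop("'gamma' must be positive")
  if (!(n > 0)) stop("'n' must be positive")
  if (n <= 1) {
    warning("Hill order n <= 1: the replication kinetics cannot be bistable")
  }
  structure(list(lam = lam, rho = rho, K = K, n = n, gamma = gamma),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Kinetic parameters (uM, hr):\n")
  cat(sprintf("  lambda = %g uM/hr, rho = %g /hr, K = %g uM, n = %g, gamma = %g /hr\n",
              x$lam, x$rho, x$K, x$n, x$gamma))
  invisible(x)
}

#' Intracellular chemical state of one cell
#'
#' @param V Soluble Sup35 concentration, uM.
#' @param S Aggregated (prion-conformation) Sup35 concentration, uM.
#'
#' @return A named numeric vector `c(V, S)` of class `cell_state`.
#' @examples
#' cell_state(0.07, 0.5)
#' @export
cell_state <- function(V, S) {
  stopifnot(is.numeric(V), length(V) == 1L, is.numeric(S), length(S) == 1L)
  if (V < 0 || S < 0) stop("concentrations must be nonnegative")
  structure(c(V = V, S = S), class = "cell_state")
}

## Coerce a state-like input (cell_state or plain length-2 numeric) to c(V, S).
as_state <- function(state) {
  x <- unclass(state)
  if (!is.numeric(x) || length(x) != 2L) {
    stop("a cell state must be a numeric vector of length 2: (V, S)")
  }
  if (any(x < 0)) stop("concentrations must be nonnegative")
  names(x) <- c("V", "S")
  x
}

#' Hill replication efficiency
#'
#' The fraction of the maximal replication rate realised at aggregate
#' concentration `S`: \eqn{f(S) = S^n / (K^n + S^n)}. Computed in log space
#' for `S > 0` so that large Hill orders do not overflow.
#'
#' @param S Aggregate concentration(s), uM; vectorised.
#' @param K Half-saturation threshold, uM.
#' @param n Hill order.
#'
#' @return Efficiency value(s) in `[0, 1]`, strictly increasing in `S`.
#' @examples
#' replication_efficiency(c(0, 1, 2), K = 1, n = 5) # 0, 0.5, 32/33
#' @export
replication_efficiency <- function(S, K, n) {
  if (any(S < 0)) stop("'S' must be nonnegative")
  if (!(K > 0)) stop("'K' must be positive")
  if (!(n > 0)) stop("'n' must be positive")
  out <- numeric(length(S))
  pos <- S > 0
  out[pos] <- 1 / (1 + exp(n * (log(K) - log(S[pos]))))
  out
}

## d f / d S; for S > 0 equals (n/S) f (1 - f). At S = 0 the limit is 0 for
## n > 1, 1/K for n = 1, and diverges for n < 1.
replication_efficiency_prime <- function(S, K, n) {
  if (S > 0) {
    f <- replication_efficiency(S, K, n)
    return(n / S * f * (1 - f))
  }
  if (n > 1) return(0)
  if (n == 1) return(1 / K)
  Inf
}

#' Right-hand side of the aggregation kinetics
#'
#' Time derivatives of the soluble (`V`) and aggregated (`S`) Sup35
#' concentrations:
#' \deqn{dV/dt = \lambda - \gamma V - \rho V f(S), \quad
#'       dS/dt = \rho V f(S) - \gamma S,}
#' with `f` the Hill efficiency of [replication_efficiency()]. The two
#' components always sum to \eqn{\lambda - \gamma (V + S)}: conversion
#' conserves total Sup35 mass.
#'
#' @param state A [cell_state()] or numeric `(V, S)`.
#' @param params A [kinetic_params()] object.
#'
#' @return Named numeric vector `c(dV, dS)` in uM/hr.
#' @examples
#' kp <- kinetic_params(gamma = 0.2554)
#' ode_rhs(cell_state(kp$lam / kp$gamma, 0), kp) # equilibrium: c(0, 0)
#' @export
ode_rhs <- function(state, params) {
  st <- as_state(state)
  stopifnot(inherits(params, "kinetic_params"))
  f <- replication_efficiency(st[["S"]], params$K, params$n)
  repl <- params$rho * st[["V"]] * f
  c(dV = params$lam - params$gamma * st[["V"]] - repl,
    dS = repl - params$gamma * st[["S"]])
}

#' Analytic Jacobian of the kinetics
#'
#' @inheritParams ode_rhs
#' @return A 2x2 numeric matrix, rows/columns ordered `(V, S)`.
#' @export
kinetics_jacobian <- function(state, params) {
  st <- as_state(state)
  V <- st[["V"]]; S <- st[["S"]]
  f <- replication_efficiency(S, params$K, params$n)
  fp <- replication_efficiency_prime(S, params$K, params$n)
  matrix(c(-params$gamma - params$rho * f, -params$rho * V * fp,
           params$rho * f,                  params$rho * V * fp - params$gamma),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("dV", "dS"), c("V", "S")))
}

new_equilibrium <- function(V, S, eigenvalues = complex(0), stability = NA_character_) {
  structure(list(state = c(V = V, S = S),
                 eigenvalues = eigenvalues,
                 stability = stability),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium: V = %.6g uM, S = %.6g uM  [%s]\n",
              x$state[["V"]], x$state[["S"]],
              ifelse(is.na(x$stability), "unclassified", x$stability)))
  invisible(x)
}

## Steady-state residual along the reduced curve V = lam/gamma - S.
## Roots of g on (0, lam/gamma] are the prion equilibria.
equilibrium_g <- function(S, params) {
  params$rho * (params$lam / params$gamma - S) *
    replication_efficiency(S, params$K, params$n) - params$gamma * S
}

#' Find all nonnegative equilibria of the kinetics
#'
#' The prion-free equilibrium \eqn{(\lambda/\gamma, 0)} always exists. Prion
#' equilibria are located on the reduced curve \eqn{V = \lambda/\gamma - S}
#' (forced by the steady state of the conserved sum \eqn{V + S}), by
#' scanning the residual for sign changes on \eqn{(0, \lambda/\gamma]} and
#' refining each bracket by bisection. For Hill order `n > 1` and a
#' replication rate above the saddle-node value this yields three equilibria
#' with stability pattern stable/unstable/stable in order of increasing `S`.
#'
#' @param params A [kinetic_params()] object.
#' @param scan_points Number of scan points on `(0, lam/gamma]`; at least 100.
#' @param tol Residual tolerance (uM/hr) used to verify each equilibrium.
#'
#' @return A list of `equilibrium` objects sorted by `S`, each classified by
#'   [classify_stability()]; class `equilibrium_set`.
#' @examples
#' kp <- kinetic_params(gamma = derive_rates(2, 3, 0.6)[["gamma_M"]])
#' eqs <- find_equilibria(kp)
#' length(eqs) # 3 for the default strong strain
#' @export
find_equilibria <- function(params, scan_points = 2000, tol = 1e-8) {
  stopifnot(inherits(params, "kinetic_params"))
  if (scan_points < 100) stop("'scan_points' must be at least 100")
  Vmax <- params$lam / params$gamma
  roots <- numeric(0)
  if (params$rho > 0) {
    grid <- seq(Vmax / scan_points, Vmax, length.out = scan_points)
    gv <- equilibrium_g(grid, params)
    sgn <- sign(gv)
    ## exact zeros on the grid count as roots themselves
    roots <- grid[gv == 0]
    flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (i in flip) {
      r <- stats::uniroot(equilibrium_g, interval = c(grid[i], grid[i + 1]),
                          params = params, tol = 1e-13)
      roots <- c(roots, r$root)
    }
  }
  roots <- sort(unique(roots))
  eqs <- list(new_equilibrium(Vmax, 0))
  for (S in roots) {
    eqs <- c(eqs, list(new_equilibrium(Vmax - S, S)))
  }
  eqs <- lapply(eqs, function(eq) {
    resid <- ode_rhs(eq$state, params)
    if (max(abs(resid)) >= tol) {
      warning(sprintf("equilibrium at S = %g has residual %g above tol %g",
                      eq$state[["S"]], max(abs(resid)), tol))
    }
    classify_stability(eq, params)
  })
  structure(eqs, class = c("equilibrium_set", "list"))
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("%d equilibria (ordered by S):\n", length(x)))
  for (eq in x) print(eq)
  invisible(x)
}

#' @describeIn find_equilibria Equilibria as a data frame with eigenvalues,
#'   suitable for CSV export.
#' @param x An `equilibrium_set`.
#' @param ... Unused.
#' @export
as.data.frame.equilibrium_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(eq) {
    data.frame(V = eq$state[["V"]], S = eq$state[["S"]],
               eig_re_1 = Re(eq$eigenvalues[1]), eig_im_1 = Im(eq$eigenvalues[1]),
               eig_re_2 = Re(eq$eigenvalues[2]), eig_im_2 = Im(eq$eigenvalues[2]),
               stability = eq$stability)
  }))
}

#' Classify the local stability of an equilibrium
#'
#' Evaluates the analytic Jacobian at the equilibrium and labels it
#' `"STABLE"` when both eigenvalue real parts are negative, `"UNSTABLE"`
#' when any is positive, and `"MARGINAL"` when an eigenvalue real part lies
#' within `tol` of zero (as at the saddle-node point itself).
#'
#' @param eq An `equilibrium` (from [find_equilibria()] or constructed with
#'   a state that zeroes [ode_rhs()]).
#' @param params A [kinetic_params()] object.
#' @param tol Half-width of the marginal band on eigenvalue real parts, 1/hr.
#' @param resid_tol Residual (uM/hr) above which the input is rejected as
#'   not an equilibrium.
#'
#' @return The equilibrium with `eigenvalues` and `stability` filled in.
#' @export
classify_stability <- function(eq, params, tol = 1e-8, resid_tol = 1e-6) {
  stopifnot(inherits(eq, "equilibrium"))
  resid <- ode_rhs(eq$state, params)
  if (max(abs(resid)) > resid_tol) {
    stop(sprintf("state (V=%g, S=%g) is not an equilibrium (residual %g)",
                 eq$state[["V"]], eq$state[["S"]], max(abs(resid))))
  }
  ev <- eigen(kinetics_jacobian(eq$state, params), only.values = TRUE)$values
  ev <- as.complex(ev)
  re <- Re(ev)
  eq$eigenvalues <- ev
  eq$stability <- if (any(abs(re) <= tol)) "MARGINAL"
                  else if (any(re > 0)) "UNSTABLE"
                  else "STABLE"
  eq
}

#' Locate the saddle-node bifurcation in the replication rate
#'
#' For fixed \eqn{\lambda, \gamma, K, n}, the two prion equilibria appear
#' through a saddle-node bifurcation as \eqn{\rho} increases. This locates
#' the critical rate by bisection on the number of equilibria returned by
#' [find_equilibria()].
#'
#' @param params A [kinetic_params()] object; its `rho` is ignored.
#' @param bracket Length-2 interval of `rho` (1/hr) whose endpoints must
#'   bracket the bifurcation (1 and 3 equilibria respectively).
#' @param rel_tol Relative tolerance on the returned critical rate.
#' @param scan_points Scan resolution passed to [find_equilibria()].
#'
#' @return The critical replication rate `rho*`, 1/hr.
#' @export
saddle_node_rho <- function(params, bracket = c(0.01, 10), rel_tol = 1e-6,
                            scan_points = 2000) {
  stopifnot(inherits(params, "kinetic_params"), length(bracket) == 2L)
  n_eq <- function(rho) {
    p <- params
    p$rho <- rho
    length(find_equilibria(p, scan_points = scan_points))
  }
  lo <- min(bracket); hi <- max(bracket)
  n_lo <- n_eq(lo); n_hi <- n_eq(hi)
  if (!(n_lo == 1 && n_hi == 3)) {
    stop(sprintf(
      "bracket endpoints must enclose the bifurcation: %g gives %d equilibria, %g gives %d",
      lo, n_lo, hi, n_hi))
  }
  while ((hi - lo) > rel_tol * hi) {
    mid <- (lo + hi) / 2
    if (n_eq(mid) >= 3) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
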