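## Core continuous-time integration. All kinetics integration in the package
## funnels through .ode_states(): an ensemble of cells sharing one parameter
## set (lambda, gamma, rho, K, n) is integrated as a single stacked ODE
## system through deSolve's compiled-model interface. The Adams
## (predictor-corrector, non-stiff) method is used: the kinetics are
## non-stiff at the rates of interest and the method never forms a Jacobian,
## so ensembles of tens of thousands of cells remain cheap.

`%||%` <- function(a, b) if (is.null(a)) b else a

ODE_RTOL <- 1e-8
ODE_ATOL <- 1e-10

## states: n x 2 matrix (V, S). Returns the n x 2 matrix at `duration` when
## `times` is NULL, otherwise a list(times=, V=, S=) with V, S of dimension
## length(times) x n. Rows with S == 0 evolve on the invariant prion-free
## manifold; the solver preserves it exactly (f(0) = 0), and a duration of 0
## is the identity.
.ode_states <- function(states, kin, gamma = kin$gamma, duration,
                        times = NULL) {
  if (duration < 0) stop("'duration' must be nonnegative")
  n <- nrow(states)
  tout <- sort(unique(c(0, times %||% numeric(0), duration)))
  if (duration == 0 || n == 0) {
    if (is.null(times)) return(states)
    return(list(times = tout,
                V = matrix(states[, 1], length(tout), n, byrow = TRUE),
                S = matrix(states[, 2], length(tout), n, byrow = TRUE)))
  }
  y0 <- as.numeric(t(states))
  out <- deSolve::ode(y = y0, times = tout, func = "prionide_derivs",
                      parms = c(kin$lam, gamma, kin$rho, kin$K, kin$n),
                      dllname = "prionide", initfunc = "prionide_initmod",
                      method = "adams", rtol = ODE_RTOL, atol = ODE_ATOL)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    stop(sprintf("ODE integration failed (istate %d) at t = %g of %g",
                 istate[1], out[nrow(out), 1], duration),
         call. = FALSE)
  }
  ## solver round-off can leave concentrations a hair below zero
  y <- pmax(unname(out[, -1, drop = FALSE]), 0)
  if (is.null(times)) {
    final <- y[nrow(y), ]
    return(matrix(final, ncol = 2, byrow = TRUE))
  }
  list(times = tout,
       V = y[, seq(1, 2 * n, by = 2), drop = FALSE],
       S = y[, seq(2, 2 * n, by = 2), drop = FALSE])
}

#' Integrate the kinetics over one continuous segment
#'
#' Solves the aggregation ODE between two division events, with relative
#' tolerance `1e-8` and absolute tolerance `1e-10` uM. The prion-free
#' manifold is exactly invariant: an input with `S = 0` returns `S = 0`.
#'
#' @param state A [cell_state()] or numeric `(V, S)`.
#' @param params A [kinetic_params()] object (its `gamma` is the dilution
#'   rate used on this segment).
#' @param duration Segment length, hr (nonnegative).
#'
#' @return The `cell_state` after `duration` hours.
#' @examples
#' kp <- kinetic_params(gamma = 0.2554)
#' integrate_segment(cell_state(0.07, 0.4), kp, 2)
#' @export
integrate_segment <- function(state, params, duration) {
  st <- as_state(state)
  stopifnot(inherits(params, "kinetic_params"))
  if (st[["S"]] == 0) {
    ## closed form on the invariant manifold: dV/dt = lam - gamma V
    Vinf <- params$lam / params$gamma
    V <- Vinf + (st[["V"]] - Vinf) * exp(-params$gamma * duration)
    return(cell_state(V, 0))
  }
  out <- .ode_states(rbind(st), params, duration = duration)
  cell_state(out[1, 1], out[1, 2])
}

## Normalise a lineage side spec to "MOTHER"/"DAUGHTER".
match_side <- function(side) {
  side <- toupper(as.character(side))
  out <- ifelse(side %in% c("MOTHER", "M"), "MOTHER",
                ifelse(side %in% c("DAUGHTER", "D"), "DAUGHTER", NA))
  if (anyNA(out)) stop("'side' must be \"MOTHER\" or \"DAUGHTER\"")
  out
}

## Cycle parameters of one lineage side: period, dilution rate and the jump
## coefficients of the offspring that the lineage keeps.
side_cycle <- function(side, div) {
  side <- match_side(side)
  if (side == "MOTHER") {
    list(side = side, T = div$T_M, gamma = div$gamma_M,
         alpha_V = div$alpha_M_V, alpha_S = div$alpha_M_S)
  } else {
    list(side = side, T = div$T_D, gamma = div$gamma_D,
         alpha_V = div$alpha_D_V, alpha_S = div$alpha_D_S)
  }
}

## Matrix form of the stroboscopic map: one full cycle of `side` applied to
## every row of `states`.
strobe_states <- function(states, side, kin, div) {
  cyc <- side_cycle(side, div)
  out <- .ode_states(states, kin, gamma = cyc$gamma, duration = cyc$T)
  out[, 1] <- (1 + cyc$alpha_V) * out[, 1]
  out[, 2] <- (1 + cyc$alpha_S) * out[, 2]
  out
}

#' Stroboscopic map of a periodic lineage
#'
#' Advances a post-division state through one full cycle of the mother-only
#' or daughter-only lineage: continuous growth/dilution for one period
#' (`T_M` with rate `gamma_M`, or `T_D` with `gamma_D`) followed by the
#' division impulse, keeping the same-side offspring. Fixed points of this
#' map are the periodic solutions of the lineage.
#'
#' @param state A [cell_state()] or numeric `(V, S)`: post-division state.
#' @param side `"MOTHER"` or `"DAUGHTER"`.
#' @param kin A [kinetic_params()] object (`gamma` is overridden by the
#'   side's growth rate).
#' @param div A [division_params()] object.
#'
#' @return The post-division `cell_state` one period later.
#' @examples
#' kin <- kinetic_params(gamma = 0.2554)
#' stroboscopic_map(cell_state(0.07, 0.5), "MOTHER", kin, division_params())
#' @export
stroboscopic_map <- function(state, side, kin, div) {
  st <- as_state(state)
  out <- strobe_states(rbind(st), side, kin, div)
  cell_state(out[1, 1], out[1, 2])
}

#' Impulse schedule of a single lineage
#'
#' Builds the fixed division-time sequence of a lineage from the sequence
#' of sides it follows: each cycle lasts `T_M` (mother side) or `T_D`
#' (daughter side), so event `k` occurs at the cumulative sum of the cycle
#' lengths.
#'
#' @param sides Character vector of `"MOTHER"`/`"DAUGHTER"` (or `"M"`/`"D"`),
#'   one per division event, in order.
#' @param div A [division_params()] object.
#' @param t0 Time of the founder's cycle start, hr.
#'
#' @return A data frame with columns `time` (hr) and `side`, of class
#'   `impulse_schedule`.
#' @examples
#' impulse_schedule(c("M", "M", "D"), division_params())
#' @export
impulse_schedule <- function(sides, div, t0 = 0) {
  sides <- match_side(sides)
  periods <- ifelse(sides == "MOTHER", div$T_M, div$T_D)
  structure(data.frame(time = t0 + cumsum(periods), side = sides,
                       stringsAsFactors = FALSE),
            class = c("impulse_schedule", "data.frame"))
}

#' @describeIn impulse_schedule Mother-only schedule covering `horizon`.
#' @param horizon Simulation horizon, hr.
#' @export
mother_only_schedule <- function(horizon, div) {
  impulse_schedule(rep("MOTHER", max(1, floor(horizon / div$T_M))), div)
}

#' @describeIn impulse_schedule Daughter-only schedule covering `horizon`.
#' @export
daughter_only_schedule <- function(horizon, div) {
  impulse_schedule(rep("DAUGHTER", max(1, floor(horizon / div$T_D))), div)
}

#' Follow one cell lineage through its division events
#'
#' Integrates the impulsive system along a single lineage: continuous
#' kinetics between divisions (with the dilution rate of the current
#' cycle's side) and a multiplicative concentration jump at each division,
#' keeping the offspring named by the event's side. The founder starts its
#' first cycle at `t = 0`.
#'
#' @param founder A [cell_state()] or numeric `(V, S)`.
#' @param schedule An [impulse_schedule()] (times strictly increasing; each
#'   inter-event gap must equal the period of the event's side).
#' @param kin A [kinetic_params()] object.
#' @param div A [division_params()] object.
#' @param horizon End of the simulation, hr; the schedule must cover it
#'   (last event no earlier than `horizon` minus one period).
#' @param n_sub Number of interior sample points recorded per segment.
#'
#' @return A `lineage_trajectory`: list with `samples` (data frame `time`,
#'   `V`, `S`, `side`, `impulse` marking left/right limits at divisions) and
#'   `post_impulse` (data frame of the post-division states that form the
#'   lineage's discrete dynamical system).
#' @examples
#' div <- division_params()
#' kin <- kinetic_params(gamma = div$gamma_M)
#' tr <- run_lineage(cell_state(0.07, 0.5), mother_only_schedule(10, div),
#'                   kin, div, horizon = 10)
#' tail(tr$post_impulse)
#' @export
run_lineage <- function(founder, schedule, kin, div, horizon, n_sub = 25) {
  st <- as_state(founder)
  stopifnot(inherits(kin, "kinetic_params"), inherits(div, "division_params"))
  times <- schedule$time
  sides <- match_side(schedule$side)
  if (is.unsorted(times, strictly = TRUE)) stop("schedule times must be strictly increasing")
  periods <- ifelse(sides == "MOTHER", div$T_M, div$T_D)
  starts <- c(0, times[-length(times)])
  if (any(abs(times - starts - periods) > 1e-9)) {
    stop("schedule inconsistent: each inter-event gap must equal the period of the event's side")
  }
  last_cover <- times[length(times)] + periods[length(periods)]
  if (last_cover < horizon - 1e-9) {
    stop(sprintf("schedule covers only %g hr of the %g hr horizon", last_cover, horizon))
  }

  samples <- list()
  post <- list(data.frame(time = 0, V = st[["V"]], S = st[["S"]],
                          side = "FOUNDER", stringsAsFactors = FALSE))
  t_cur <- 0
  for (k in seq_along(times)) {
    if (t_cur >= horizon) break
    cyc <- side_cycle(sides[k], div)
    seg_end <- min(times[k], horizon)
    dur <- seg_end - t_cur
    sub <- seq(0, dur, length.out = n_sub + 2)
    sol <- .ode_states(rbind(st), kin, gamma = cyc$gamma, duration = dur,
                       times = sub)
    seg <- data.frame(time = t_cur + sol$times, V = sol$V[, 1], S = sol$S[, 1],
                      side = sides[k],
                      impulse = "none", stringsAsFactors = FALSE)
    st <- c(V = sol$V[nrow(sol$V), 1], S = sol$S[nrow(sol$S), 1])
    if (times[k] <= horizon) {
      seg$impulse[nrow(seg)] <- "left"
      st <- c(V = (1 + cyc$alpha_V) * st[["V"]],
              S = (1 + cyc$alpha_S) * st[["S"]])
      seg <- rbind(seg, data.frame(time = times[k], V = st[["V"]], S = st[["S"]],
                                   side = sides[k], impulse = "right",
                                   stringsAsFactors = FALSE))
      post <- c(post, list(data.frame(time = times[k], V = st[["V"]],
                                      S = st[["S"]], side = sides[k],
                                      stringsAsFactors = FALSE)))
    }
    samples <- c(samples, list(seg))
    t_cur <- times[k]
  }
  ## tail segment beyond the last processed event, up to the horizon
  if (t_cur < horizon) {
    k <- length(sides)
    cyc <- side_cycle(sides[k], div)
    dur <- horizon - t_cur
    sub <- seq(0, dur, length.out = n_sub + 2)
    sol <- .ode_states(rbind(st), kin, gamma = cyc$gamma, duration = dur,
                       times = sub)
    samples <- c(samples, list(
      data.frame(time = t_cur + sol$times, V = sol$V[, 1], S = sol$S[, 1],
                 side = sides[k], impulse = "none", stringsAsFactors = FALSE)))
  }
  structure(list(samples = do.call(rbind, samples),
                 post_impulse = do.call(rbind, post),
                 founder = as_state(founder), horizon = horizon),
            class = "lineage_trajectory")
}

#' @export
print.lineage_trajectory <- function(x, ...) {
  np <- nrow(x$post_impulse) - 1
  last <- x$post_impulse[nrow(x$post_impulse), ]
  cat(sprintf(
    "Lineage trajectory: founder (V=%g, S=%g) uM, %d divisions over %g hr\n",
    x$founder[["V"]], x$founder[["S"]], np, x$horizon))
  cat(sprintf("  last post-division state: V=%.6g, S=%.6g uM at t=%g hr\n",
              last$V, last$S, last$time))
  invisible(x)
}

#' Write a lineage trajectory to CSV
#'
#' @param trajectory A `lineage_trajectory` from [run_lineage()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- trajectory$samples
  df$is_impulse <- df$impulse != "none"
  utils::write.csv(df[, c("time", "V", "S", "is_impulse", "side")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Finite-difference Jacobian of the stroboscopic map at each row of
## `states` (central differences, step `h` uM), batched into one solver
## call. Returns a list of 2x2 matrices.
strobe_jacobians <- function(states, side, kin, div, h = 1e-6) {
  n <- nrow(states)
  stack <- matrix(0, 4 * n, 2)
  for (i in seq_len(n)) {
    x <- states[i, ]
    stack[4 * i - 3, ] <- pmax(x + c(h, 0), 0)
    stack[4 * i - 2, ] <- pmax(x - c(h, 0), 0)
    stack[4 * i - 1, ] <- pmax(x + c(0, h), 0)
    stack[4 * i, ]     <- pmax(x - c(0, h), 0)
  }
  out <- strobe_states(stack, side, kin, div)
  lapply(seq_len(n), function(i) {
    dV <- (out[4 * i - 3, ] - out[4 * i - 2, ]) /
      (stack[4 * i - 3, 1] - stack[4 * i - 2, 1])
    dS <- (out[4 * i - 1, ] - out[4 * i, ]) /
      (stack[4 * i - 1, 2] - stack[4 * i, 2])
    cbind(dV, dS)
  })
}

#' Periodic solutions of the mother-only or daughter-only lineage
#'
#' Finds the fixed points of the lineage's stroboscopic map, which are the
#' periodic solutions of the periodically-impulsed system. The prion-free
#' fixed point on the `S = 0` axis is obtained in closed form (the axis map
#' is affine in `V`); further fixed points are located by a damped Newton
#' iteration on `map(x) - x` started from every point of a seed grid, with
#' the map Jacobian estimated by central finite differences (step `1e-6`
#' uM). Floquet multipliers are the eigenvalues of that Jacobian: a fixed
#' point is `STABLE` when both multipliers lie strictly inside the unit
#' circle.
#'
#' @inheritParams stroboscopic_map
#' @param seed_grid Matrix of seed states (columns `V`, `S`); default a
#'   10 x 10 grid over `[0, 2 lam/gamma]^2`.
#' @param fp_tol Convergence tolerance on `|map(x) - x|`, uM.
#' @param dedup_tol Distance below which two fixed points are merged, uM.
#' @param max_iter Newton iteration cap per seed.
#'
#' @return A list of `periodic_solution` objects (fields `state`, `period`,
#'   `side`, `multipliers`, `stability`), sorted by `S`; class
#'   `periodic_solution_set`. Seeds whose iteration does not converge are
#'   dropped (with a message when `verbose`).
#' @param verbose Report dropped seeds.
#' @examples
#' div <- division_params()
#' kin <- kinetic_params(gamma = div$gamma_M)
#' ps <- find_periodic_solutions("MOTHER", kin, div)
#' sapply(ps, function(p) p$stability)
#' @export
find_periodic_solutions <- function(side, kin, div, seed_grid = NULL,
                                    fp_tol = 1e-10, dedup_tol = 1e-6,
                                    max_iter = 60, verbose = FALSE) {
  side <- match_side(side)
  cyc <- side_cycle(side, div)
  span <- 2 * kin$lam / cyc$gamma
  if (is.null(seed_grid)) {
    ax <- seq(0, span, length.out = 10)
    seed_grid <- as.matrix(expand.grid(V = ax, S = ax))
  }
  seeds <- unname(as.matrix(seed_grid))

  ## closed-form prion-free fixed point: on the axis the map is
  ## V -> (1+aV) * (Vinf + (V - Vinf) e^(-gT))
  Vinf <- kin$lam / cyc$gamma
  aV <- cyc$alpha_V
  decay <- exp(-cyc$gamma * cyc$T)
  V_free <- (1 + aV) * Vinf * (1 - decay) / (1 - (1 + aV) * decay)
  fps <- rbind(c(V_free, 0))

  ## synchronous damped Newton across all seeds, batched per iteration;
  ## returns the matrix of converged points (possibly 0 rows)
  newton_fps <- function(seeds) {
    x <- seeds
    found <- matrix(0, 0, 2)
    active <- rep(TRUE, nrow(x))
    n_left <- 0
    Fx <- strobe_states(x, side, kin, div) - x
    for (iter in seq_len(max_iter)) {
      if (!any(active)) break
      idx <- which(active)
      J <- strobe_jacobians(x[idx, , drop = FALSE], side, kin, div)
      for (j in seq_along(idx)) {
        i <- idx[j]
        A <- J[[j]] - diag(2)
        step <- tryCatch(solve(A, -Fx[i, ]), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) {
          active[i] <- FALSE
          n_left <- n_left + 1
          next
        }
        ## damp long steps; keep iterates in the nonnegative quadrant
        sl <- sqrt(sum(step^2))
        if (sl > span / 2) step <- step * (span / 2) / sl
        x[i, ] <- pmax(x[i, ] + step, 0)
      }
      idx <- which(active)
      Fx[idx, ] <- strobe_states(x[idx, , drop = FALSE], side, kin, div) -
        x[idx, , drop = FALSE]
      for (i in idx) {
        if (sqrt(sum(Fx[i, ]^2)) < fp_tol) {
          found <- rbind(found, x[i, ])
          active[i] <- FALSE
        }
      }
    }
    if (verbose && (any(active) || n_left > 0)) {
      message(sprintf("%d seed(s) did not converge and were dropped",
                      sum(active) + n_left))
    }
    found
  }

  fps <- rbind(fps, newton_fps(seeds))
  ## saddle points between two attractors have narrow Newton basins; re-seed
  ## at midpoints of every pair of distinct fixed points located so far
  uniq <- fps[!duplicated(round(fps, 4)), , drop = FALSE]
  if (nrow(uniq) > 1) {
    pairs <- utils::combn(nrow(uniq), 2)
    mids <- t(apply(pairs, 2, function(p) (uniq[p[1], ] + uniq[p[2], ]) / 2))
    fps <- rbind(fps, newton_fps(mids))
  }

  ## deduplicate (the analytic axis point wins ties)
  keep <- rbind(fps[1, ])
  for (i in seq_len(nrow(fps))[-1]) {
    d <- sqrt(rowSums((keep - matrix(fps[i, ], nrow(keep), 2, byrow = TRUE))^2))
    if (all(d > dedup_tol)) keep <- rbind(keep, fps[i, ])
  }
  keep <- keep[order(keep[, 2], keep[, 1]), , drop = FALSE]

  Js <- strobe_jacobians(keep, side, kin, div)
  sols <- lapply(seq_len(nrow(keep)), function(i) {
    mult <- as.complex(eigen(Js[[i]], only.values = TRUE)$values)
    mod <- Mod(mult)
    stability <- if (any(abs(mod - 1) <= 1e-6)) "MARGINAL"
                 else if (all(mod < 1)) "STABLE" else "UNSTABLE"
    structure(list(state = c(V = keep[i, 1], S = keep[i, 2]),
                   period = cyc$T, side = side,
                   multipliers = mult, stability = stability),
              class = "periodic_solution")
  })
  structure(sols, class = c("periodic_solution_set", "list"))
}

#' @export
print.periodic_solution <- function(x, ...) {
  cat(sprintf("Periodic solution (%s, period %g hr): V=%.6g, S=%.6g uM [%s], |multipliers| = %.4g, %.4g\n",
              x$side, x$period, x$state[["V"]], x$state[["S"]], x$stability,
              Mod(x$multipliers[1]), Mod(x$multipliers[2])))
  invisible(x)
}

#' @export
print.periodic_solution_set <- function(x, ...) {
  cat(sprintf("%d periodic solution(s):\n", length(x)))
  for (p in x) print(p)
  invisible(x)
}

#' Export periodic solutions to a JSON report
#'
#' @param solutions A `periodic_solution_set`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_periodic_solutions_json <- function(solutions, path) {
  rep <- lapply(solutions, function(p) {
    list(side = p$side, period_hr = p$period,
         V = unname(p$state[["V"]]), S = unname(p$state[["S"]]),
         multiplier_mod = Mod(p$multipliers), stability = p$stability)
  })
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Internal ensemble fate classifier: founders is an n x 2 matrix of
## post-division states; returns list(fate = character vector, periods =
## iteration count at classification, final = states). Shared by
## lineage_fate() and the phenotype map.
lineage_fate_states <- function(founders, side, kin, div, max_periods = 500,
                                tol = 1e-6, prion_floor = 1e-6,
                                fixed_points = NULL) {
  side <- match_side(side)
  fps <- fixed_points %||% find_periodic_solutions(side, kin, div)
  free_fp <- NULL
  prion_fp <- NULL
  for (p in fps) {
    if (p$state[["S"]] <= prion_floor) {
      free_fp <- p$state
    } else if (p$stability == "STABLE") {
      if (is.null(prion_fp) || p$state[["S"]] > prion_fp[["S"]]) prion_fp <- p$state
    }
  }
  if (is.null(free_fp)) stop("no prion-free fixed point available")

  n <- nrow(founders)
  fate <- rep("UNDECIDED", n)
  periods <- rep(NA_integer_, n)
  x <- founders

  classify <- function(x, iter) {
    idx <- which(fate == "UNDECIDED")
    if (!length(idx)) return(invisible())
    xi <- x[idx, , drop = FALSE]
    d_free <- sqrt((xi[, 1] - free_fp[["V"]])^2 + (xi[, 2] - free_fp[["S"]])^2)
    is_free <- xi[, 2] < prion_floor | d_free < tol
    fate[idx[is_free]] <<- "FREE"
    periods[idx[is_free]] <<- iter
    if (!is.null(prion_fp)) {
      d_pr <- sqrt((xi[, 1] - prion_fp[["V"]])^2 + (xi[, 2] - prion_fp[["S"]])^2)
      is_pr <- !is_free & d_pr < tol
      fate[idx[is_pr]] <<- "PRION"
      periods[idx[is_pr]] <<- iter
    }
    invisible()
  }

  classify(x, 0L)
  for (iter in seq_len(max_periods)) {
    idx <- which(fate == "UNDECIDED")
    if (!length(idx)) break
    x[idx, ] <- strobe_states(x[idx, , drop = FALSE], side, kin, div)
    classify(x, iter)
  }
  list(fate = fate, periods = periods, final = x,
       free_fp = free_fp, prion_fp = prion_fp)
}

#' Asymptotic fate of one lineage
#'
#' Iterates the stroboscopic map from a founder's state and reports whether
#' the lineage is cured (`"FREE"`: the post-division aggregate
#' concentration falls below `prion_floor`, or the state converges to the
#' prion-free fixed point) or keeps the prion (`"PRION"`: convergence to
#' the stable prion fixed point). If neither basin is entered within
#' `max_periods` cycles the result is `"UNDECIDED"` — reported, never
#' coerced.
#'
#' @inheritParams stroboscopic_map
#' @param founder A [cell_state()] or numeric `(V, S)`.
#' @param max_periods Iteration cap (number of division cycles).
#' @param tol Convergence distance to a fixed point, uM.
#' @param prion_floor Aggregate concentration below which a lineage is
#'   considered cured, uM. Numerically `S` never reaches exactly zero; the
#'   floor operationalises curing.
#' @param fixed_points Optional precomputed [find_periodic_solutions()]
#'   result for this side (cache for repeated calls).
#'
#' @return One of `"FREE"`, `"PRION"`, `"UNDECIDED"`.
#' @examples
#' div <- division_params()
#' kin <- kinetic_params(gamma = div$gamma_M)
#' lineage_fate(cell_state(0.07, 0.3), "MOTHER", kin, div) # "FREE"
#' @export
lineage_fate <- function(founder, side, kin, div, max_periods = 500,
                         tol = 1e-6, prion_floor = 1e-6,
                         fixed_points = NULL) {
  if (max_periods < 1) stop("'max_periods' must be at least 1")
  st <- as_state(founder)
  res <- lineage_fate_states(rbind(st), side, kin, div,
                             max_periods = max_periods, tol = tol,
                             prion_floor = prion_floor,
                             fixed_points = fixed_points)
  res$fate[1]
}
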