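#' In-silico guanidine hydrochloride curing experiment
#'
#' Grows a colony from a prion-positive founder under treated kinetics —
#' GdnHCl is modeled as a strong reduction of the aggregate replication
#' rate `rho`, not a complete block — and records the prion-positive cell
#' count, the total cell count and their ratio over time. When the treated
#' mother-only lineage keeps the prion while every daughter branched from
#' it cures, the prion-positive count saturates (the propagon plateau)
#' while the colony keeps growing exponentially.
#'
#' @param founder A [cell_state()] or numeric `(V, S)`; must score
#'   prion-positive (`S >= score_threshold`) at time 0. A natural choice is
#'   the stable prion periodic state of the untreated strain.
#' @param kin_treated A [kinetic_params()] object with the treated
#'   (reduced) replication rate.
#' @param div A [division_params()] object.
#' @param horizon Duration of the treatment, hr.
#' @param score_threshold Aggregate concentration scoring a cell
#'   prion-positive, uM.
#' @param prune_floor Pruning floor passed to [simulate_colony()].
#' @param sample_dt Sample grid spacing, hr.
#' @param window Plateau-detection window passed to [detect_phases()], hr.
#'
#' @return A `curing_curves` object: data frame columns `time`,
#'   `prion_count`, `total_count`, `prion_fraction`, with the detected
#'   `phases` and run parameters as attributes-style list fields.
#' @examples
#' div <- division_params()
#' treated <- kinetic_params(rho = 0.18, gamma = div$gamma_M)
#' cc <- propagon_curing(cell_state(0.07, 4.2), treated, div, horizon = 30)
#' cc$phases$plateau
#' @export
propagon_curing <- function(founder, kin_treated, div, horizon = 40,
                            score_threshold = 0.5, prune_floor = 1e-4,
                            sample_dt = 0.1, window = 6) {
  st <- as_state(founder)
  if (st[["S"]] < score_threshold) {
    stop(sprintf(
      "founder must be prion-positive at t = 0: S = %g uM is below the score threshold %g uM",
      st[["S"]], score_threshold))
  }
  col <- simulate_colony(st, kin_treated, div, horizon = horizon,
                         prune_floor = prune_floor,
                         score_threshold = score_threshold,
                         sample_dt = sample_dt)
  curves <- structure(
    list(times = col$record$time,
         prion_count = col$record$prion_cells,
         total_count = col$record$total_cells,
         prion_fraction = col$record$prion_fraction,
         colony = col, window = window,
         score_threshold = score_threshold),
    class = "curing_curves")
  curves$phases <- detect_phases(curves, window = window)
  curves
}

#' @export
print.curing_curves <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Curing curves over %g hr (%d samples)\n", max(x$times), n))
  cat(sprintf("  final: %d prion-positive of %d cells (fraction %.2e)\n",
              as.integer(x$prion_count[n]), as.integer(x$total_count[n]),
              x$prion_fraction[n]))
  ph <- x$phases
  if (!is.null(ph)) {
    cat(sprintf("  phase 1 (lag): [%g, %g] hr\n", ph$lag[1], ph$lag[2]))
    cat(sprintf("  phase 2 (decline): [%g, %g] hr\n", ph$decline[1], ph$decline[2]))
    if (is.null(ph[["plateau"]])) cat("  phase 3 (plateau): not reached\n")
    else cat(sprintf("  phase 3 (plateau): [%g, %g] hr\n",
                     ph[["plateau"]][1], ph[["plateau"]][2]))
  }
  invisible(x)
}

#' Detect the three phases of a curing curve
#'
#' Splits a curing experiment into the three canonical phases: (1) a lag
#' in which every cell is still prion-positive and the prion count grows
#' with the colony, ending at the first sample where the prion fraction
#' drops below `1 - 1e-6`; (3) the plateau, beginning at the first time
#' after which the prion count never changes by one cell or more between
#' samples one `window` apart; (2) the decline in between.
#'
#' The division schedule makes the simulated count a deterministic,
#' periodically-modulated signal (period `lcm(T_M, T_D)` for commensurate
#' cycle times), so the plateau test compares phase-matched samples one
#' window apart rather than the raw range; the default window of 6 hr is
#' one full period of the reference timings `T_M = 2`, `T_D = 3`.
#'
#' @param curves A `curing_curves` object (or compatible list with
#'   `times`, `prion_count`, `prion_fraction`).
#' @param window Trailing comparison window, hr.
#'
#' @return List with `lag`, `decline` (length-2 time intervals, hr) and
#'   `plateau` (interval, or `NULL` with `plateau_reached = FALSE` when no
#'   plateau occurs within the horizon).
#' @export
detect_phases <- function(curves, window = 6) {
  times <- curves$times
  count <- curves$prion_count
  frac <- curves$prion_fraction
  horizon <- max(times)
  if (horizon < 3 * window) {
    stop("curves must span at least three detection windows")
  }
  ## phase 1: all cells prion-positive
  drop_idx <- which(frac < 1 - 1e-6)
  t1 <- if (length(drop_idx)) times[drop_idx[1]] else horizon

  ## phase 3: the trailing-window mean count changes by less than one cell
  ## between consecutive windows, from some time on. The windowed mean
  ## absorbs the deterministic periodic modulation of the count (period
  ## lcm(T_M, T_D) for commensurate cycle times) and the sample-bin flicker
  ## of threshold-grazing cells. The sample grid is uniform, so the lag is
  ## an exact integer offset.
  dt <- stats::median(diff(times))
  k <- as.integer(round(window / dt))
  if (abs(k * dt - window) > 1e-6) {
    stop("'window' must be a multiple of the sample spacing")
  }
  csum <- cumsum(count)
  idx <- seq_along(times)
  wmean <- rep(NA_real_, length(times))
  has_w <- idx > k
  wmean[has_w] <- (csum[idx[has_w]] - csum[idx[has_w] - k]) / k
  valid <- idx > 2 * k
  change <- rep(NA_real_, length(times))
  change[valid] <- abs(wmean[idx[valid]] - wmean[idx[valid] - k])
  ok <- valid & change < 1
  ## earliest t3 with every later comparison below one cell
  bad <- which(valid & !ok)
  t3 <- if (length(bad)) {
    nxt <- times[bad[length(bad)]] + min(diff(times))
    if (nxt > horizon - 1e-9) NA_real_ else nxt
  } else {
    times[which(valid)[1]] - window
  }
  t3 <- if (!is.na(t3)) max(t3, t1) else t3

  phases <- list(lag = c(0, t1))
  if (is.na(t3) || t1 >= horizon) {
    phases$decline <- c(t1, horizon)
    phases$plateau <- NULL
    phases$plateau_reached <- FALSE
  } else {
    phases$decline <- c(t1, t3)
    phases$plateau <- c(t3, horizon)
    phases$plateau_reached <- TRUE
  }
  phases
}

#' Propagon count from the curing plateau
#'
#' The prion-positive cell count averaged over the detected plateau phase,
#' rounded to the nearest integer — the model's analogue of the propagon
#' count inferred from curing experiments.
#'
#' @param curves A `curing_curves` object with a detected plateau.
#' @return Integer cell count.
#' @export
plateau_value <- function(curves) {
  ph <- curves$phases
  if (is.null(ph) || !isTRUE(ph$plateau_reached)) {
    stop("no plateau was detected within the horizon")
  }
  sel <- curves$times >= ph$plateau[1] - 1e-9
  as.integer(round(mean(curves$prion_count[sel])))
}

#' Asymptotic growth exponent of the division schedule
#'
#' The colony's cell count grows like `exp(beta * t)` with `beta` solving
#' `exp(-beta * T_M) + exp(-beta * T_D) = 1` (each division replaces one
#' cell by a mother-cycle and a daughter-cycle cell).
#'
#' @param T_M,T_D Cycle durations, hr.
#' @return Growth exponent, 1/hr.
#' @examples
#' colony_growth_exponent(2, 3) # ~0.2812
#' @export
colony_growth_exponent <- function(T_M = 2, T_D = 3) {
  stats::uniroot(function(b) exp(-b * T_M) + exp(-b * T_D) - 1,
                 c(1e-6, 10), tol = 1e-12)$root
}

#' Write curing curves to CSV
#'
#' @param curves A `curing_curves` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_curing_csv <- function(curves, path) {
  utils::write.csv(
    data.frame(time = curves$times, prion_count = curves$prion_count,
               total_count = curves$total_count,
               prion_fraction = curves$prion_fraction),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the detected curing phases to JSON
#'
#' @param curves A `curing_curves` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phases_json <- function(curves, path) {
  ph <- curves$phases
  rep <- list(lag_hr = ph$lag, decline_hr = ph$decline,
              plateau_reached = isTRUE(ph$plateau_reached))
  if (isTRUE(ph$plateau_reached)) {
    rep$plateau_hr <- ph$plateau
    rep$plateau_cells <- plateau_value(curves)
  }
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
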