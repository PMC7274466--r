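## Whole-colony simulation. Division timing is independent of the chemistry
## (cells divide on fixed schedules set by T_M and T_D alone), so the
## division-time lattice {a*T_M + b*T_D} is known in advance. The simulator
## exploits this twice: cells dividing at the same instant on the same cycle
## type share birth time, duration and dilution rate and are integrated as
## one ensemble; and the cell-count bookkeeping of pruned (cured) subtrees
## reduces to a pure timing recurrence with no chemistry at all.

TIME_KEY_DIGITS <- 9

time_key <- function(t) sprintf("%.*f", TIME_KEY_DIGITS, t)

## Timing-only division recurrence on the lattice a*T_M + b*T_D: every
## division spawns one mother-cycle and one daughter-cycle cell. Returns a
## step function of cells alive at time tau >= 0 (birth-inclusive,
## division-exclusive) for a founder starting a cycle of `first_cycle` type
## at tau = 0, as list(times, alive): alive[i] holds on
## [times[i], times[i+1]).
timing_step_fun <- function(T_M, T_D, horizon, first_cycle = c("M", "D")) {
  first_cycle <- match.arg(first_cycle)
  a_max <- floor(horizon / T_M + 1e-9)
  b_max <- floor(horizon / T_D + 1e-9)
  lat <- outer(seq(0, a_max) * T_M, seq(0, b_max) * T_D, "+")
  lat <- sort(unique(round(as.numeric(lat), TIME_KEY_DIGITS)))
  lat <- lat[lat <= horizon + 1e-9]
  idx <- new.env(hash = TRUE)
  for (i in seq_along(lat)) assign(time_key(lat[i]), i, envir = idx)
  lookup <- function(t) {
    k <- time_key(t)
    if (exists(k, envir = idx, inherits = FALSE)) get(k, envir = idx) else NA_integer_
  }
  nM <- numeric(length(lat))
  nD <- numeric(length(lat))
  divs <- numeric(length(lat))
  if (first_cycle == "M") nM[1] <- 1 else nD[1] <- 1
  for (i in seq_along(lat)[-1]) {
    t <- lat[i]
    from_M <- lookup(t - T_M)
    from_D <- lookup(t - T_D)
    d <- (if (!is.na(from_M)) nM[from_M] else 0) +
         (if (!is.na(from_D)) nD[from_D] else 0)
    divs[i] <- d
    nM[i] <- d
    nD[i] <- d
  }
  list(times = lat, alive = 1 + cumsum(divs))
}

eval_step_fun <- function(sf, tau) {
  out <- numeric(length(tau))
  pos <- tau >= -1e-9
  i <- findInterval(tau[pos] + 1e-9, sf$times)
  out[pos] <- sf$alive[pmax(i, 1)]
  out
}

#' Closed-form cell count of the division schedule
#'
#' Number of cells alive at `horizon` in a colony grown from one founder
#' that starts a mother cycle at time 0, counting by the pure timing
#' recurrence (every division produces one mother-cycle and one
#' daughter-cycle cell; lifetimes are half-open `[birth, division)`).
#' Intracellular chemistry has no effect on division timing, so this is an
#' exact oracle for the population size of [simulate_colony()].
#'
#' @param horizon Time at which cells are counted, hr.
#' @param T_M,T_D Mother and daughter cycle durations, hr.
#'
#' @return Cell count (numeric: counts exceed integer range for long
#'   horizons).
#' @examples
#' cell_count_oracle(7, 2, 3) # 7 cells
#' @export
cell_count_oracle <- function(horizon, T_M = 2, T_D = 3) {
  if (horizon < 0) stop("'horizon' must be nonnegative")
  sf <- timing_step_fun(T_M, T_D, horizon, "M")
  round(eval_step_fun(sf, horizon))
}

## Growable column store for cell-cycle nodes.
new_node_store <- function(n0 = 256L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$cap <- n0
  for (f in c("parent", "birth", "cycle", "side", "V0", "S0",
              "end", "V_end", "S_end", "divided", "pruned")) {
    assign(f, rep(NA_real_, n0), envir = env)
  }
  env$cycle <- rep(NA_character_, n0)
  env$side <- rep(NA_character_, n0)
  env$divided <- rep(FALSE, n0)
  env$pruned <- rep(FALSE, n0)
  env
}

store_grow <- function(st, need) {
  while (st$cap < need) {
    new_cap <- st$cap * 2L
    for (f in c("parent", "birth", "V0", "S0", "end", "V_end", "S_end")) {
      v <- get(f, envir = st)
      length(v) <- new_cap
      assign(f, v, envir = st)
    }
    for (f in c("cycle", "side")) {
      v <- get(f, envir = st)
      length(v) <- new_cap
      assign(f, v, envir = st)
    }
    for (f in c("divided", "pruned")) {
      v <- get(f, envir = st)
      v2 <- rep(FALSE, new_cap)
      v2[seq_along(v)] <- v
      assign(f, v2, envir = st)
    }
    st$cap <- new_cap
  }
}

store_add <- function(st, parent, birth, cycle, side, V0, S0, end) {
  k <- length(parent)
  store_grow(st, st$n + k)
  i <- st$n + seq_len(k)
  st$parent[i] <- parent
  st$birth[i] <- birth
  st$cycle[i] <- cycle
  st$side[i] <- side
  st$V0[i] <- V0
  st$S0[i] <- S0
  st$end[i] <- end
  st$n <- st$n + k
  i
}

#' Simulate a whole yeast colony from one founder cell
#'
#' Event-driven simulation of the full binary lineage tree: every cell
#' integrates the aggregation kinetics over its cycle (mother cycles last
#' `T_M` with dilution `gamma_M`, daughter first cycles `T_D` with
#' `gamma_D`) and divides on schedule, splitting concentrations with the
#' partition coefficients of [apply_division()]. Division timing is
#' unaffected by the chemistry. A cell is scored prion-positive at a sample
#' time when its aggregate concentration is at least `score_threshold`.
#'
#' Subtrees whose root is born with `S` below `prune_floor` are not
#' simulated: below the bistable barrier the aggregate concentration only
#' decays, every descendant cures, and the subtree's contribution to the
#' population count follows the timing-only recurrence of
#' [cell_count_oracle()]. `prune_floor = 0` disables pruning.
#'
#' @param founder A [cell_state()] or numeric `(V, S)`.
#' @param kin A [kinetic_params()] object (per-cycle dilution rates come
#'   from `div`).
#' @param div A [division_params()] object.
#' @param horizon Simulation end, hr.
#' @param prune_floor Aggregate concentration (uM) below which a newborn
#'   cell's subtree is pruned and counted analytically.
#' @param score_threshold Aggregate concentration (uM) at or above which a
#'   cell is scored prion-positive.
#' @param sample_dt Spacing of the record's sample grid, hr.
#' @param founder_cycle `"mother"` (default) or `"daughter"`: the cycle type
#'   of the founder's first division.
#' @param max_cells Hard cap on simulated cells; exceeding it raises an
#'   error advising pruning or a shorter horizon.
#'
#' @return An object of class `colony`: list with `nodes` (data frame of
#'   cell-cycle nodes: id, parent, birth, cycle, side at birth, state at
#'   birth, end time, state at end, divided/pruned flags), `record` (a
#'   `colony_record` data frame: time, total_cells, prion_cells,
#'   prion_fraction) and the run parameters.
#' @examples
#' div <- division_params()
#' kin <- kinetic_params(gamma = div$gamma_M)
#' col <- simulate_colony(cell_state(0.07, 0.6), kin, div, horizon = 8)
#' tail(col$record)
#' @export
simulate_colony <- function(founder, kin, div, horizon,
                            prune_floor = 0, score_threshold = 0.5,
                            sample_dt = 0.1,
                            founder_cycle = c("mother", "daughter"),
                            max_cells = 5e6) {
  st0 <- as_state(founder)
  founder_cycle <- match.arg(founder_cycle)
  stopifnot(inherits(kin, "kinetic_params"), inherits(div, "division_params"))
  if (!(horizon > 0)) stop("'horizon' must be positive")
  if (prune_floor == 0) {
    projected <- cell_count_oracle(horizon, div$T_M, div$T_D)
    if (projected > max_cells) {
      stop(sprintf(
        "projected colony size %.0f exceeds max_cells = %g; enable pruning or shorten the horizon",
        projected, max_cells))
    }
  }

  sample_times <- seq(0, horizon, by = sample_dt)
  n_samp <- length(sample_times)
  prion_at <- numeric(n_samp)
  pruned_extra <- numeric(n_samp) # cells contributed by pruned subtrees

  cyc_of <- function(cycle) {
    if (cycle == "M") list(T = div$T_M, gamma = div$gamma_M)
    else list(T = div$T_D, gamma = div$gamma_D)
  }
  ## step functions for pruned-subtree counting, built lazily
  sfs <- list(M = NULL, D = NULL)
  get_sf <- function(cycle) {
    if (is.null(sfs[[cycle]])) {
      sfs[[cycle]] <<- timing_step_fun(div$T_M, div$T_D, horizon, cycle)
    }
    sfs[[cycle]]
  }

  st <- new_node_store()
  first_cyc <- if (founder_cycle == "mother") "M" else "D"
  store_add(st, parent = NA_real_, birth = 0, cycle = first_cyc,
            side = "FOUNDER", V0 = st0[["V"]], S0 = st0[["S"]],
            end = cyc_of(first_cyc)$T)

  ## frontier: ids of nodes not yet processed
  frontier <- 1L
  repeat {
    if (!length(frontier)) break
    ends <- st$end[frontier]
    dividing <- ends <= horizon + 1e-9
    if (!any(dividing)) break
    t_next <- min(ends[dividing])
    take <- frontier[dividing & abs(ends - t_next) < 1e-9]
    frontier <- setdiff(frontier, take)

    for (cycle in unique(st$cycle[take])) {
      ids <- take[st$cycle[take] == cycle]
      cc <- cyc_of(cycle)
      birth <- t_next - cc$T
      ## sample offsets inside [birth, t_next)
      in_cycle <- which(sample_times >= birth - 1e-9 &
                          sample_times < t_next - 1e-9)
      offs <- sample_times[in_cycle] - birth
      states <- cbind(st$V0[ids], st$S0[ids])
      sol <- .ode_states(states, kin, gamma = cc$gamma, duration = cc$T,
                         times = offs)
      if (length(in_cycle)) {
        rows <- match(round(offs, TIME_KEY_DIGITS), round(sol$times, TIME_KEY_DIGITS))
        prion_at[in_cycle] <- prion_at[in_cycle] +
          rowSums(sol$S[rows, , drop = FALSE] >= score_threshold)
      }
      last <- length(sol$times)
      V_end <- sol$V[last, ]
      S_end <- sol$S[last, ]
      st$V_end[ids] <- V_end
      st$S_end[ids] <- S_end
      st$divided[ids] <- TRUE

      ## division impulses, vectorised over the batch
      kids <- list(
        M = list(V = (1 + div$alpha_M_V) * V_end, S = (1 + div$alpha_M_S) * S_end,
                 side = "MOTHER"),
        D = list(V = (1 + div$alpha_D_V) * V_end, S = (1 + div$alpha_D_S) * S_end,
                 side = "DAUGHTER"))
      for (kc in c("M", "D")) {
        kd <- kids[[kc]]
        keep <- prune_floor <= 0 | kd$S >= prune_floor
        ## pruned children: analytic timing contribution, no chemistry
        if (any(!keep)) {
          np <- sum(!keep)
          sf <- get_sf(kc)
          later <- which(sample_times >= t_next - 1e-9)
          if (length(later)) {
            pruned_extra[later] <- pruned_extra[later] +
              np * eval_step_fun(sf, sample_times[later] - t_next)
          }
          pr_ids <- store_add(st, parent = ids[!keep], birth = t_next,
                              cycle = kc, side = kd$side, V0 = kd$V[!keep],
                              S0 = kd$S[!keep], end = t_next + cyc_of(kc)$T)
          st$pruned[pr_ids] <- TRUE
        }
        if (any(keep)) {
          new_ids <- store_add(st, parent = ids[keep], birth = t_next,
                               cycle = kc, side = kd$side,
                               V0 = kd$V[keep], S0 = kd$S[keep],
                               end = t_next + cyc_of(kc)$T)
          frontier <- c(frontier, new_ids)
        }
      }
      if (st$n > max_cells) {
        stop(sprintf(
          "colony exceeded max_cells = %g; enable pruning or shorten the horizon",
          max_cells))
      }
    }
  }

  ## terminal (unfinished) cycles: integrate from birth to horizon for
  ## prion scoring, grouped by (birth, cycle)
  if (length(frontier)) {
    groups <- split(frontier, paste(time_key(st$birth[frontier]), st$cycle[frontier]))
    for (g in groups) {
      cycle <- st$cycle[g[1]]
      cc <- cyc_of(cycle)
      birth <- st$birth[g[1]]
      in_cycle <- which(sample_times >= birth - 1e-9)
      offs <- sample_times[in_cycle] - birth
      states <- cbind(st$V0[g], st$S0[g])
      sol <- .ode_states(states, kin, gamma = cc$gamma,
                         duration = max(offs, 0), times = offs)
      if (length(in_cycle)) {
        rows <- match(round(offs, TIME_KEY_DIGITS), round(sol$times, TIME_KEY_DIGITS))
        prion_at[in_cycle] <- prion_at[in_cycle] +
          rowSums(sol$S[rows, , drop = FALSE] >= score_threshold)
      }
      last <- length(sol$times)
      st$V_end[g] <- sol$V[last, ]
      st$S_end[g] <- sol$S[last, ]
    }
  }

  n <- st$n
  nodes <- data.frame(
    id = seq_len(n), parent = st$parent[seq_len(n)],
    birth = st$birth[seq_len(n)], cycle = st$cycle[seq_len(n)],
    side = st$side[seq_len(n)], V0 = st$V0[seq_len(n)], S0 = st$S0[seq_len(n)],
    end = st$end[seq_len(n)], V_end = st$V_end[seq_len(n)],
    S_end = st$S_end[seq_len(n)], divided = st$divided[seq_len(n)],
    pruned = st$pruned[seq_len(n)], stringsAsFactors = FALSE)

  ## total simulated cells alive at each sample time (half-open lifetimes),
  ## by difference accumulation over the uniform grid
  delta <- numeric(n_samp + 1)
  live <- nodes[!nodes$pruned, ]
  i1 <- findInterval(live$birth - 1e-9, sample_times) + 1
  end_eff <- ifelse(live$divided, live$end, Inf)
  i2 <- findInterval(end_eff - 1e-9, sample_times) # last sample < end
  ok <- i2 >= i1
  for (j in which(ok)) {
    delta[i1[j]] <- delta[i1[j]] + 1
    delta[i2[j] + 1] <- delta[i2[j] + 1] - 1
  }
  total_at <- cumsum(delta[seq_len(n_samp)]) + pruned_extra

  record <- structure(
    data.frame(time = sample_times, total_cells = total_at,
               prion_cells = prion_at,
               prion_fraction = ifelse(total_at > 0, prion_at / total_at, NA)),
    class = c("colony_record", "data.frame"))

  structure(list(nodes = nodes, record = record,
                 founder = st0, kin = kin, div = div, horizon = horizon,
                 prune_floor = prune_floor, score_threshold = score_threshold,
                 sample_dt = sample_dt, founder_cycle = founder_cycle),
            class = "colony")
}

#' @export
print.colony <- function(x, ...) {
  final <- x$record[nrow(x$record), ]
  cat(sprintf("Colony: founder (V=%g, S=%g) uM, horizon %g hr\n",
              x$founder[["V"]], x$founder[["S"]], x$horizon))
  cat(sprintf("  %d cell-cycle nodes simulated (%d pruned subtree roots)\n",
              nrow(x$nodes), sum(x$nodes$pruned)))
  cat(sprintf("  final: %d cells, %d prion-positive (fraction %.3f)\n",
              as.integer(final$total_cells), as.integer(final$prion_cells),
              final$prion_fraction))
  invisible(x)
}

#' Write a colony record to CSV
#'
#' @param colony A `colony` (or its `record`).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_colony_csv <- function(colony, path) {
  rec <- if (inherits(colony, "colony")) colony$record else colony
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export the lineage tree in Newick format
#'
#' Serialises the colony's binary lineage tree: each node is one cell
#' cycle, branch lengths are cycle lifetimes in hours, and tip/node labels
#' carry the cell id, the aggregate concentration at birth and a
#' prion-positivity flag (`S` at birth against the colony's score
#' threshold), in the form `c<id>_S<value>_p<0|1>`.
#'
#' @param colony A `colony` from [simulate_colony()].
#' @param digits Significant digits for the S annotation.
#'
#' @return A single Newick string (terminated by `;`).
#' @examples
#' div <- division_params()
#' kin <- kinetic_params(gamma = div$gamma_M)
#' col <- simulate_colony(cell_state(2.5, 0), kin, div, horizon = 4.5)
#' export_lineage_tree(col)
#' @export
export_lineage_tree <- function(colony, digits = 4) {
  stopifnot(inherits(colony, "colony"))
  nodes <- colony$nodes
  thr <- colony$score_threshold
  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  label <- sprintf("c%d_S%.*g_p%d", nodes$id, digits, nodes$S0,
                   as.integer(nodes$S0 >= thr))
  blen <- ifelse(nodes$divided, nodes$end, colony$horizon) - nodes$birth
  rec <- function(i) {
    ch <- kids[[as.character(i)]]
    body <- if (length(ch)) {
      paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")")
    } else ""
    sprintf("%s%s:%.*g", body, label[i], 10, blen[i])
  }
  root <- nodes$id[is.na(nodes$parent)]
  ch <- kids[[as.character(root)]]
  if (!length(ch)) {
    return(sprintf("%s;", label[root]))
  }
  sprintf("(%s)%s;", paste(vapply(ch, rec, character(1)), collapse = ","),
          label[root])
}
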