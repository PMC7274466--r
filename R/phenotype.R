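#' Colony phenotype of a founder cell
#'
#' Classifies the colony grown from a founder at `(V0, S0)` by the
#' asymptotic fates of the two extreme lineages. The mother-only lineage
#' retains aggregates best and the daughter-only lineage worst, so the two
#' bracket every lineage in the colony:
#' * `FREE` — the mother-only lineage cures: every lineage cures, a fully
#'   prion-free (dark red) colony;
#' * `PRION` — the daughter-only lineage keeps the prion: every lineage
#'   does, a fully prion-positive (white) colony;
#' * `SECTORED` — the mother-only lineage keeps the prion but the
#'   daughter-only lineage cures: a mixed colony;
#' * `UNDECIDED` — a needed lineage did not resolve within `max_periods`.
#'
#' The combination mother-FREE with daughter-PRION contradicts the
#' retention bias towards mothers and is raised as a consistency error.
#'
#' @inheritParams lineage_fate
#' @param V0,S0 Founder concentrations, uM.
#' @param mother_fp,daughter_fp Optional [find_periodic_solutions()] caches
#'   for the two sides.
#'
#' @return One of `"FREE"`, `"PRION"`, `"SECTORED"`, `"UNDECIDED"`.
#' @examples
#' div <- division_params()
#' kin <- kinetic_params(gamma = div$gamma_M)
#' classify_founder(0.7, 0.4, kin, div) # "SECTORED"
#' @export
classify_founder <- function(V0, S0, kin, div, max_periods = 500, tol = 1e-6,
                             prion_floor = 1e-6, mother_fp = NULL,
                             daughter_fp = NULL) {
  if (V0 < 0 || S0 < 0) stop("founder concentrations must be nonnegative")
  fm <- lineage_fate(c(V0, S0), "MOTHER", kin, div, max_periods = max_periods,
                     tol = tol, prion_floor = prion_floor,
                     fixed_points = mother_fp)
  fd <- lineage_fate(c(V0, S0), "DAUGHTER", kin, div,
                     max_periods = max_periods, tol = tol,
                     prion_floor = prion_floor, fixed_points = daughter_fp)
  combine_fates(fm, fd)
}

combine_fates <- function(mother, daughter) {
  out <- character(length(mother))
  bad <- mother == "FREE" & daughter == "PRION"
  if (any(bad)) {
    stop(sprintf(paste0(
      "model-consistency error: %d founder(s) have a cured mother-only ",
      "lineage but a prion daughter-only lineage, which contradicts the ",
      "mother-retention bias"), sum(bad)))
  }
  out[mother == "FREE"] <- "FREE"
  out[daughter == "PRION"] <- "PRION"
  out[mother == "PRION" & daughter == "FREE"] <- "SECTORED"
  out[out == ""] <- "UNDECIDED"
  out
}

#' Phenotype map over founder states
#'
#' Classifies every founder on a grid of the `(V0, S0)` plane with
#' [classify_founder()], computing the periodic solutions of each lineage
#' side once and reusing them for all grid points. The four periodic
#' solutions (prion-free and prion, mother and daughter side) are attached
#' for overlay on the map.
#'
#' @inheritParams classify_founder
#' @param kin A [kinetic_params()] object.
#' @param div A [division_params()] object.
#' @param V_grid,S_grid Numeric grids, uM; default 100 equally spaced
#'   points on `[0, 1.2 lam/gamma_M]` (the physically reachable region plus
#'   the division-impulse inflation).
#'
#' @return A `phenotype_map`: list with `V_grid`, `S_grid`, `labels` (a
#'   `length(V_grid) x length(S_grid)` character matrix), `periodic`
#'   (solutions of both sides), `undecided` (coordinates of unresolved
#'   founders, if any) and the parameters.
#' @examples
#' div <- division_params()
#' kin <- kinetic_params(gamma = div$gamma_M)
#' pm <- phenotype_map(kin, div, V_grid = seq(0, 3, length.out = 12),
#'                     S_grid = seq(0, 3, length.out = 12))
#' table(pm$labels)
#' @export
phenotype_map <- function(kin, div, V_grid = NULL, S_grid = NULL,
                          max_periods = 500, tol = 1e-6, prion_floor = 1e-6) {
  stopifnot(inherits(kin, "kinetic_params"), inherits(div, "division_params"))
  span <- 1.2 * kin$lam / div$gamma_M
  V_grid <- V_grid %||% seq(0, span, length.out = 100)
  S_grid <- S_grid %||% seq(0, span, length.out = 100)
  founders <- as.matrix(expand.grid(V = V_grid, S = S_grid))

  fps <- list(MOTHER = find_periodic_solutions("MOTHER", kin, div),
              DAUGHTER = find_periodic_solutions("DAUGHTER", kin, div))
  fm <- lineage_fate_states(founders, "MOTHER", kin, div,
                            max_periods = max_periods, tol = tol,
                            prion_floor = prion_floor,
                            fixed_points = fps$MOTHER)$fate
  fd <- lineage_fate_states(founders, "DAUGHTER", kin, div,
                            max_periods = max_periods, tol = tol,
                            prion_floor = prion_floor,
                            fixed_points = fps$DAUGHTER)$fate
  labels <- combine_fates(fm, fd)
  undecided <- founders[labels == "UNDECIDED", , drop = FALSE]
  structure(list(V_grid = V_grid, S_grid = S_grid,
                 labels = matrix(labels, nrow = length(V_grid),
                                 dimnames = NULL),
                 periodic = fps, undecided = undecided,
                 kin = kin, div = div,
                 max_periods = max_periods, tol = tol,
                 prion_floor = prion_floor),
            class = "phenotype_map")
}

#' @export
print.phenotype_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("FREE", "SECTORED", "PRION", "UNDECIDED")))
  cat(sprintf("Phenotype map: %d x %d founders on [%g, %g] x [%g, %g] uM\n",
              length(x$V_grid), length(x$S_grid),
              min(x$V_grid), max(x$V_grid), min(x$S_grid), max(x$S_grid)))
  print(tab)
  invisible(x)
}

#' @describeIn phenotype_map Long-format data frame (V, S, label).
#' @param x A `phenotype_map`.
#' @param ... Unused.
#' @export
as.data.frame.phenotype_map <- function(x, ...) {
  data.frame(V = rep(x$V_grid, times = length(x$S_grid)),
             S = rep(x$S_grid, each = length(x$V_grid)),
             label = as.vector(x$labels), stringsAsFactors = FALSE)
}

#' Fraction of the founder grid leading to sectored colonies
#'
#' @param map A [phenotype_map()].
#' @return Fraction of grid points labeled `SECTORED`, in `[0, 1]`.
#' @export
sectored_area_fraction <- function(map) {
  stopifnot(inherits(map, "phenotype_map"))
  mean(map$labels == "SECTORED")
}

#' Write a phenotype map to CSV
#'
#' @param map A `phenotype_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phenotype_map_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phenotype map (labels plus periodic-solution overlay) to JSON
#'
#' @param map A `phenotype_map`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_phenotype_map_json <- function(map, path) {
  overlay <- lapply(map$periodic, function(set) {
    lapply(set, function(p) list(side = p$side, V = unname(p$state[["V"]]),
                                 S = unname(p$state[["S"]]),
                                 stability = p$stability))
  })
  jsonlite::write_json(
    list(V_grid = map$V_grid, S_grid = map$S_grid,
         labels = map$labels, periodic_solutions = overlay,
         undecided = map$undecided),
    path, auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}
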