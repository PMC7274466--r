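test_that("segment integration matches a fixed-step RK4 reference", {
  for (case in list(list(st = c(0.07, 0.4), dur = 2),
                    list(st = c(1.5, 1.0), dur = 3),
                    list(st = c(2.7, 0.05), dur = 1.3))) {
    got <- integrate_segment(case$st, fix_kin, case$dur)
    ref <- rk4_oracle(case$st, fix_kin, fix_kin$gamma, case$dur)
    expect_lt(max(abs(unclass(got) - ref)), 1e-6)
  }
})

test_that("segment integration fixes equilibria and the zero-duration map", {
  eqst <- c(fix_kin$lam / fix_kin$gamma, 0)
  out <- integrate_segment(eqst, fix_kin, 5)
  expect_equal(unname(unclass(out)), eqst, tolerance = 1e-10)
  st <- c(0.3, 0.9)
  expect_equal(unname(unclass(integrate_segment(st, fix_kin, 0))), st)
  expect_error(integrate_segment(st, fix_kin, -1), "nonnegative")
})

test_that("the prion-free manifold is exactly invariant", {
  out <- integrate_segment(c(0.2, 0), fix_kin, 7)
  expect_identical(out[["S"]], 0)
  ## also through the ensemble path used by the stroboscopic map
  m <- prionide:::strobe_states(rbind(c(0.2, 0), c(1.5, 0)), "MOTHER",
                                fix_kin, fix_div)
  expect_identical(unname(m[, 2]), c(0, 0))
  ## and along a whole lineage
  tr <- run_lineage(c(1, 0), mother_only_schedule(10, fix_div),
                    fix_kin, fix_div, horizon = 10)
  expect_true(all(tr$samples$S == 0))
})

test_that("lineage simulation and the stroboscopic map agree", {
  horizon <- 12
  tr <- run_lineage(c(0.07, 0.5), mother_only_schedule(horizon, fix_div),
                    fix_kin, fix_div, horizon = horizon)
  x <- c(0.07, 0.5)
  for (k in seq_len(nrow(tr$post_impulse) - 1)) {
    x <- unclass(stroboscopic_map(x, "MOTHER", fix_kin, fix_div))
    expect_lt(max(abs(x - as.numeric(tr$post_impulse[k + 1, c("V", "S")]))),
              1e-6)
  }
  ## piecewise record: one left and one right value per impulse
  imp <- tr$samples[tr$samples$impulse != "none", ]
  expect_equal(nrow(imp), 2 * (nrow(tr$post_impulse) - 1))
  expect_true(all(tr$samples$V >= 0 & tr$samples$S >= 0))
})

test_that("schedules are validated against sides and horizon", {
  sched <- impulse_schedule(c("M", "M", "D"), fix_div)
  expect_equal(sched$time, c(2, 4, 7))
  bad <- sched
  bad$time[2] <- 3.5
  expect_error(run_lineage(c(1, 1), bad, fix_kin, fix_div, horizon = 7),
               "inconsistent")
  expect_error(run_lineage(c(1, 1), impulse_schedule("M", fix_div),
                           fix_kin, fix_div, horizon = 10),
               "covers")
  expect_error(impulse_schedule("X", fix_div), "side")
})

test_that("prion-free axis fixed point matches its closed form", {
  for (side in c("MOTHER", "DAUGHTER")) {
    cyc <- prionide:::side_cycle(side, fix_div)
    Vinf <- fix_kin$lam / cyc$gamma
    decay <- exp(-cyc$gamma * cyc$T)
    V_free <- Vinf * (1 - decay) / (1 - decay) # eps_V = 0: plain relaxation
    sols <- if (side == "MOTHER") fix_ps_mother else fix_ps_daughter
    free <- Filter(function(p) p$state[["S"]] == 0, sols)
    expect_length(free, 1)
    expect_equal(free[[1]]$state[["V"]], Vinf, tolerance = 1e-9)
    ## the axis maps to itself
    img <- stroboscopic_map(c(Vinf, 0), side, fix_kin, fix_div)
    expect_identical(img[["S"]], 0)
    expect_equal(img[["V"]], Vinf, tolerance = 1e-9)
  }
})

test_that("strong strain has two stable periodic solutions per lineage", {
  for (sols in list(fix_ps_mother, fix_ps_daughter)) {
    stable <- Filter(function(p) p$stability == "STABLE", sols)
    expect_length(stable, 2)
    S <- vapply(stable, function(p) p$state[["S"]], 0)
    expect_equal(sum(S == 0), 1) # one prion-free, one prion solution
    expect_gt(max(S), 1)
  }
  ## pooled across the two periodic systems: four stable solutions
  pooled <- c(fix_ps_mother, fix_ps_daughter)
  expect_equal(sum(fp_stabilities(pooled) == "STABLE"), 4)
  ## every returned solution is a genuine fixed point of its map
  for (p in pooled) {
    img <- stroboscopic_map(p$state, p$side, fix_kin, fix_div)
    expect_lt(sqrt(sum((unclass(img) - p$state)^2)), 1e-9)
  }
})

test_that("the weak strain's mother map exposes the saddle fixed point", {
  sols <- find_periodic_solutions("MOTHER", fix_kin_weak, fix_div)
  expect_length(sols, 3)
  expect_identical(fp_stabilities(sols), c("STABLE", "UNSTABLE", "STABLE"))
  expect_gt(max(Mod(sols[[2]]$multipliers)), 1)
  expect_true(all(Mod(sols[[1]]$multipliers) < 1))
  expect_true(all(Mod(sols[[3]]$multipliers) < 1))
})

test_that("stability labels are confirmed by perturb-and-iterate", {
  ## stable prion solution: a small perturbation decays back
  prion <- stable_prion_state(fix_ps_mother)
  x <- prion + c(1e-3, 1e-3)
  for (i in 1:50) x <- unclass(stroboscopic_map(x, "MOTHER", fix_kin, fix_div))
  expect_lt(sqrt(sum((x - prion)^2)), 1e-6)
  ## unstable (saddle) solution of the weak strain: a generic perturbation
  ## leaves its neighbourhood
  weak <- find_periodic_solutions("MOTHER", fix_kin_weak, fix_div)
  saddle <- weak[[2]]$state
  x <- saddle + c(0, 1e-3)
  for (i in 1:50) x <- unclass(stroboscopic_map(x, "MOTHER", fix_kin_weak, fix_div))
  expect_gt(sqrt(sum((x - saddle)^2)), 1e-2)
})

test_that("the stroboscopic map is monotone in the aggregate concentration", {
  for (side in c("MOTHER", "DAUGHTER")) {
    for (V in c(0.07, 1, 2.5)) {
      S <- seq(0, 3, length.out = 9)
      out <- prionide:::strobe_states(cbind(V, S), side, fix_kin, fix_div)
      expect_true(all(diff(out[, 2]) > -1e-12))
    }
  }
})

test_that("lineage fate separates the basins of the two periodic solutions", {
  ## the prion-free axis always cures
  expect_identical(lineage_fate(c(1.3, 0), "MOTHER", fix_kin, fix_div,
                                fixed_points = fix_ps_mother), "FREE")
  ## the stable prion state stays prion
  prion <- stable_prion_state(fix_ps_mother)
  expect_identical(lineage_fate(prion, "MOTHER", fix_kin, fix_div,
                                fixed_points = fix_ps_mother), "PRION")
  ## low aggregate load cures (reference strain, mother lineage)
  expect_identical(lineage_fate(c(0.07, 0.3), "MOTHER", fix_kin, fix_div,
                                fixed_points = fix_ps_mother), "FREE")
  expect_error(lineage_fate(c(1, 1), "MOTHER", fix_kin, fix_div,
                            max_periods = 0), "max_periods")
})

test_that("trajectories and periodic solutions serialise to CSV and JSON", {
  tr <- run_lineage(c(0.07, 0.5), mother_only_schedule(6, fix_div),
                    fix_kin, fix_div, horizon = 6)
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  df <- read.csv(csv)
  expect_identical(names(df), c("time", "V", "S", "is_impulse", "side"))
  expect_true(any(df$is_impulse))
  js <- tempfile(fileext = ".json")
  write_periodic_solutions_json(fix_ps_mother, js)
  rep <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(rep), length(fix_ps_mother))
  expect_true(all(rep$stability %in% c("STABLE", "UNSTABLE", "MARGINAL")))
})
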