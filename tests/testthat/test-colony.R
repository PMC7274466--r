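test_that("the timing oracle reproduces hand-enumerated division schedules", {
  expect_equal(cell_count_oracle(1.9, 2, 3), 1)
  expect_equal(cell_count_oracle(0, 2, 3), 1)
  ## hand enumeration for 7 hr, T_M = 2, T_D = 3:
  ## t=2: M[2,4) D[2,5); t=4: M[4,6) D[4,7); t=5: M[5,7) D[5,8);
  ## t=6: M[6,8) D[6,9); t=7: D[4,7) and M[5,7) divide -> 4 newborns
  ## alive at 7: D[5,8), M[6,8), D[6,9) + 4 newborns = 7
  expect_equal(cell_count_oracle(7, 2, 3), 7)
  ## symmetric division doubles every cycle
  expect_equal(cell_count_oracle(6, 2, 2), 8)
})

test_that("colony cell counts equal the timing-only oracle at every sample", {
  col <- simulate_colony(c(0.07, 0.45), fix_kin, fix_div, horizon = 16)
  oracle <- vapply(col$record$time, cell_count_oracle,
                   T_M = fix_div$T_M, T_D = fix_div$T_D, 0)
  expect_equal(col$record$total_cells, oracle)
  expect_true(all(diff(col$record$total_cells) >= 0))
  expect_equal(col$record$prion_fraction,
               col$record$prion_cells / col$record$total_cells)
})

test_that("colony growth is asymptotically exponential with the schedule's rate", {
  col <- simulate_colony(c(2.5, 0), fix_kin, fix_div, horizon = 22)
  rec <- col$record[col$record$time >= 10, ]
  slope <- coef(lm(log(rec$total_cells) ~ rec$time))[[2]]
  beta <- colony_growth_exponent(fix_div$T_M, fix_div$T_D)
  expect_equal(slope, beta, tolerance = 0.02)
})

test_that("a prion-free founder yields a fully prion-free colony", {
  col <- simulate_colony(c(2.5, 0), fix_kin, fix_div, horizon = 12)
  expect_true(all(col$record$prion_cells == 0))
  expect_true(all(col$nodes$S0 == 0))
})

test_that("volume-weighted aggregate mass is conserved at every division", {
  col <- simulate_colony(c(0.07, 0.45), fix_kin, fix_div, horizon = 14)
  nodes <- col$nodes
  divd <- nodes[nodes$divided, ]
  kids <- split(seq_len(nrow(nodes)), nodes$parent)
  pi <- fix_div$pi
  for (i in seq_len(nrow(divd))) {
    ch <- nodes[kids[[as.character(divd$id[i])]], ]
    m <- ch[ch$side == "MOTHER", ]
    d <- ch[ch$side == "DAUGHTER", ]
    expect_equal(pi * m$S0 + (1 - pi) * d$S0, divd$S_end[i], tolerance = 1e-10)
    expect_equal(pi * m$V0 + (1 - pi) * d$V0, divd$V_end[i], tolerance = 1e-10)
  }
})

test_that("founder aggregate load drives cured, sectored and full colonies", {
  cured <- simulate_colony(c(0.07, 0.3), fix_kin, fix_div, horizon = 20)
  expect_equal(tail(cured$record$prion_cells, 1), 0)
  full <- simulate_colony(c(0.07, 0.6), fix_kin, fix_div, horizon = 20)
  expect_true(all(full$record$prion_fraction == 1))
  sect <- simulate_colony(c(0.07, 0.45), fix_kin, fix_div, horizon = 20)
  final <- tail(sect$record$prion_fraction, 1)
  expect_gt(final, 0)
  expect_lt(final, 1)
  ## prion fraction at the horizon is non-decreasing in the founder load
  finals <- vapply(c(0.3, 0.45, 0.6), function(S0) {
    tail(simulate_colony(c(0.07, S0), fix_kin, fix_div,
                         horizon = 14)$record$prion_fraction, 1)
  }, 0)
  expect_true(all(diff(finals) >= 0))
})

test_that("pruned and unpruned colonies produce identical records", {
  kin <- kinetic_params(rho = 0.18, gamma = fix_div$gamma_M)
  full <- simulate_colony(c(0.07, 4), kin, fix_div, horizon = 24,
                          prune_floor = 0)
  pruned <- simulate_colony(c(0.07, 4), kin, fix_div, horizon = 24,
                            prune_floor = 0.01)
  expect_gt(sum(pruned$nodes$pruned), 0)
  expect_lt(nrow(pruned$nodes), nrow(full$nodes))
  expect_identical(pruned$record$total_cells, full$record$total_cells)
  expect_identical(pruned$record$prion_cells, full$record$prion_cells)
  ## every pruned subtree root starts below the floor, far under the
  ## bistable barrier, so no descendant can re-cross the scoring threshold
  expect_true(all(pruned$nodes$S0[pruned$nodes$pruned] < 0.01))
})

test_that("the founder's first cycle convention shifts the schedule", {
  col <- simulate_colony(c(1, 0.2), fix_kin, fix_div, horizon = 5,
                         founder_cycle = "daughter")
  expect_identical(col$nodes$cycle[1], "D")
  expect_equal(col$nodes$end[1], fix_div$T_D)
  ## daughter-first founder divides later: fewer cells at a short horizon
  colm <- simulate_colony(c(1, 0.2), fix_kin, fix_div, horizon = 5)
  expect_lt(tail(col$record$total_cells, 1), tail(colm$record$total_cells, 1))
})

test_that("oversized colonies are refused with advice", {
  expect_error(simulate_colony(c(1, 1), fix_kin, fix_div, horizon = 100,
                               max_cells = 1e4),
               "pruning|horizon")
})

test_that("exported Newick trees round-trip through an independent parser", {
  ## unbudded founder: a single labelled leaf
  lone <- simulate_colony(c(1, 0.1), fix_kin, fix_div, horizon = 1.5)
  expect_match(export_lineage_tree(lone), "^c1_S0.1_p0;$")
  ## one division: two leaves with (T_M, T_D)-consistent branch lengths
  one <- simulate_colony(c(1, 0.1), fix_kin, fix_div, horizon = 4.5)
  tr1 <- ape::read.tree(text = export_lineage_tree(one))
  expect_equal(ape::Ntip(tr1), 3) # mother cycle split again at t = 4
  col <- simulate_colony(c(0.07, 0.45), fix_kin, fix_div, horizon = 9)
  nwk <- export_lineage_tree(col)
  tree <- ape::read.tree(text = nwk)
  nodes <- col$nodes
  leaves <- nodes[!nodes$id %in% nodes$parent, ]
  expect_equal(ape::Ntip(tree), nrow(leaves))
  expect_equal(ape::Nnode(tree), sum(nodes$divided))
  ## branch lengths recover the cell lifetimes
  expect_equal(sort(tree$edge.length),
               sort(ifelse(nodes$divided, nodes$end,
                           col$horizon)[-1] - nodes$birth[-1]),
               tolerance = 1e-8)
  ## leaf annotations carry the aggregate state at birth
  expect_true(all(grepl("^c\\d+_S[-0-9.e]+_p[01]$", tree$tip.label)))
})

test_that("colony records serialise to CSV", {
  col <- simulate_colony(c(0.07, 0.6), fix_kin, fix_div, horizon = 6)
  csv <- tempfile(fileext = ".csv")
  write_colony_csv(col, csv)
  df <- read.csv(csv)
  expect_identical(names(df),
                   c("time", "total_cells", "prion_cells", "prion_fraction"))
  expect_equal(nrow(df), nrow(col$record))
})
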