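test_that("sweeps evaluate the analytic chain at every grid point", {
  sw <- sweep_fitness("d_E0", grid_size = 11)
  expect_s3_class(sw, "sweep_table")
  expect_equal(nrow(sw), 11 * 4)
  expect_true(all(diff(attr(sw, "grid")) > 0))
  # spot-check one row against a direct evaluation
  p <- fig_defaults(d_E0 = attr(sw, "grid")[6])
  direct <- evaluate_fitness(p, default_allocation("S3", "unconstrained"),
                             "S3")
  row <- sw[sw$scenario == "S3" & sw$value == attr(sw, "grid")[6], ]
  expect_equal(row$W, direct$W, tolerance = 1e-12)
  expect_equal(row$d_A, direct$d_A, tolerance = 1e-12)
  # all four curves strictly decreasing in baseline egg mortality
  for (id in c("S1", "S2", "S3", "S4")) {
    expect_true(all(diff(sw$W[sw$scenario == id]) < 0))
  }
})

test_that("sweep ranges must stay inside the parameter domain", {
  expect_error(sweep_fitness("d_E0", range = c(-0.1, 0.5)), "valid")
  expect_error(sweep_fitness("r_0", range = c(0.5, 1.2)), "valid")
  expect_no_error(sweep_fitness("b", range = c(1, 500), grid_size = 5))
})

test_that("rank_scenarios returns a permutation and flags exact ties", {
  sw <- sweep_fitness("d_E0", grid_size = 7)
  rk <- rank_scenarios(sw)
  expect_equal(nrow(rk), 7)
  ranks <- as.matrix(rk[, paste0("rank_", c("S1", "S2", "S3", "S4"))])
  for (i in seq_len(nrow(ranks))) {
    expect_setequal(ranks[i, ], 1:4)
  }
  # at r_0 = 1, S1 ties S2 and S3 ties S4
  sw1 <- sweep_fitness("d_E0", grid_size = 5,
                       params = fig_defaults(r_0 = 1))
  rk1 <- rank_scenarios(sw1)
  expect_true(all(grepl("S1=S2|S2=S1", rk1$ordering)))
})

test_that("ranking is invariant along b sweeps (linearity in b)", {
  for (kind in c("unconstrained", "constrained")) {
    sw <- sweep_fitness("b", grid_size = 9, regime = kind)
    rk <- rank_scenarios(sw)
    expect_length(unique(rk$ordering), 1L)
    expect_identical(nrow(find_crossovers(sw)), 0L)
    # fitness proportional to the grid
    for (id in c("S1", "S4")) {
      w <- sw$W[sw$scenario == id]
      expect_equal(w / sw$value[sw$scenario == id],
                   rep((w / sw$value[sw$scenario == id])[1], length(w)),
                   tolerance = 1e-12)
    }
  }
})

test_that("bisection crossovers agree with a brute-force fine grid", {
  sw <- sweep_fitness("d_A0", grid_size = 33)
  cx <- find_crossovers(sw, tol = 1e-6)
  pair <- cx[cx$scenario_a == "S2" & cx$scenario_b == "S4", ]
  expect_equal(nrow(pair), 1L)
  expect_gt(pair$location, 0)
  expect_lt(pair$location, 0.5)
  expect_identical(pair$leader_before, "S2")
  expect_identical(pair$leader_after, "S4")

  # oracle: locate the same sign change on a 1e4-point grid
  grid <- seq(0.01, 0.99, length.out = 1e4)
  w2 <- vapply(grid, function(v) {
    evaluate_fitness(fig_defaults(d_A0 = v),
                     default_allocation("S2", "unconstrained"), "S2")$W
  }, numeric(1))
  w4 <- vapply(grid, function(v) {
    evaluate_fitness(fig_defaults(d_A0 = v),
                     default_allocation("S4", "unconstrained"), "S4")$W
  }, numeric(1))
  flip <- which(sign(w2 - w4)[-1] * sign(w2 - w4)[-1e4] < 0)
  expect_length(flip, 1L)
  # bisection location must fall inside the bracketing fine-grid cell
  expect_gte(pair$location, grid[flip] - 1e-6)
  expect_lte(pair$location, grid[flip + 1] + 1e-6)
})

test_that("constrained adult-mortality sweep has no S2/S4 crossover", {
  sw <- sweep_fitness("d_A0", grid_size = 33, regime = "constrained")
  cx <- find_crossovers(sw)
  expect_false(any(cx$scenario_a == "S2" & cx$scenario_b == "S4"))
  rk <- rank_scenarios(sw)
  expect_true(all(rk$rank_S2 == 1))
})

test_that("investment curves hold the other trait fixed and respect scenarios", {
  cv <- investment_curve("c", grid_size = 21, other_level = 0.5)
  expect_equal(sort(unique(cv$scenario)), c("S1", "S2", "S3", "S4"))
  expect_true(all(cv$m[cv$scenario %in% c("S1", "S2")] == 0))
  expect_true(all(cv$m[cv$scenario %in% c("S3", "S4")] == 0.5))
  # all curves increase in c at moderately high baseline egg mortality
  for (id in unique(cv$scenario)) {
    expect_true(all(diff(cv$W[cv$scenario == id]) > 0))
  }
  # mating-trait curve: S4 above S3 everywhere
  cm <- investment_curve("m", grid_size = 21, other_level = 0.5)
  expect_true(all(cm$W[cm$scenario == "S4"] > cm$W[cm$scenario == "S3"]))
  # degenerate single-point range equals a direct evaluation
  cv0 <- investment_curve("c", range = c(0, 0), scenarios = "S1")
  expect_equal(nrow(cv0), 1L)
  expect_equal(cv0$W,
               evaluate_fitness(fig_defaults(), trait_allocation(0, 0),
                                "S1")$W)
  expect_error(investment_curve("m", scenarios = c("S1", "S3")),
               "without a mating trait")
})

test_that("fitness surfaces match pointwise evaluation and rise along both axes", {
  cg <- seq(0, 1, length.out = 6)
  mg <- seq(0, 1, length.out = 5)
  fs <- fitness_surface("S3", c_grid = cg, m_grid = mg)
  W <- attr(fs, "W_matrix")
  expect_equal(dim(W), c(6L, 5L))
  expect_equal(W[3, 4],
               evaluate_fitness(fig_defaults(),
                                trait_allocation(cg[3], mg[4]), "S3")$W)
  # at the reference parameters fitness increases along both axes (S3)
  expect_true(all(apply(W, 2, function(col) all(diff(col) > 0))))
  expect_true(all(apply(W, 1, function(row) all(diff(row) > 0))))
  # S4: care steeper than the mating trait at matched points
  fs4 <- fitness_surface("S4", c_grid = cg, m_grid = cg)
  W4 <- attr(fs4, "W_matrix")
  dc <- diff(W4[, 1]) # along c at m = 0
  dm <- diff(W4[1, ]) # along m at c = 0
  expect_true(all(dc > dm))
  # 1x1 grid collapses to a single evaluation
  fs1 <- fitness_surface("S4", c_grid = 0.5, m_grid = 0.5)
  expect_equal(fs1$W, hand_W[["S4"]], tolerance = 1e-6)
})

test_that("monotonicity verdicts match the qualitative regime structure", {
  # care without preferences: direction flips with baseline egg mortality
  expect_identical(
    classify_monotonicity("c", "S1",
                          params = fig_defaults(d_E0 = 0.9))$verdict,
    "increasing")
  expect_identical(
    classify_monotonicity("c", "S1",
                          params = fig_defaults(d_E0 = 0.02))$verdict,
    "decreasing")
  # preferred care: increasing across all baseline egg mortalities
  for (de in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
    expect_identical(
      classify_monotonicity("c", "S2",
                            params = fig_defaults(d_E0 = de))$verdict,
      "increasing")
  }
  # the mating trait pays only when baseline fertilization is low
  expect_identical(
    classify_monotonicity("m", "S3",
                          params = fig_defaults(r_0 = 0.05))$verdict,
    "increasing")
  expect_identical(
    classify_monotonicity("m", "S3",
                          params = fig_defaults(r_0 = 0.95))$verdict,
    "decreasing")
  # verdicts do not depend on the gamete count (linearity in b)
  for (b in c(1, 10, 200)) {
    expect_identical(
      classify_monotonicity("c", "S1",
                            params = fig_defaults(d_E0 = 0.9, b = b))$verdict,
      "increasing")
  }
  # flat: zero gametes give identically zero fitness
  expect_identical(
    classify_monotonicity("c", "S1", params = fig_defaults(b = 0))$verdict,
    "flat")
})
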