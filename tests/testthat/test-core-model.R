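test_that("adult mortality matches hand-evaluated closed forms and bounds", {
  p <- fig_defaults()
  a_care <- trait_allocation(c = 0.5)
  a_both <- trait_allocation(c = 0.5, m = 0.5)

  # identity / degenerate cases
  expect_equal(adult_mortality(fig_defaults(d_A0 = 1), a_care, "S1"), 1)
  expect_equal(
    adult_mortality(fig_defaults(d_A0 = 0.5, d_E0 = 1),
                    trait_allocation(c = 0), "S1"),
    0.5
  )

  # hand evaluations: 1 - 0.5 e^{-1} and 1 - 0.5 e^{-1.5}
  expect_equal(adult_mortality(p, a_care, "S1"), 1 - 0.5 * exp(-1),
               tolerance = 1e-12)
  expect_equal(adult_mortality(p, a_both, "S4"), 1 - 0.5 * exp(-1.5),
               tolerance = 1e-12)

  # the mating trait is only costly when exhibited: S1/S2 ignore m
  expect_equal(adult_mortality(p, a_both, "S1"),
               adult_mortality(p, a_care, "S1"))

  # monotonicity and range over random parameter sets
  set.seed(42)
  for (i in 1:200) {
    rp <- random_params()
    cc <- runif(1); mm <- runif(1)
    dA <- adult_mortality(rp, trait_allocation(cc, mm), "S4")
    expect_gte(dA, rp$d_A0)
    expect_lte(dA, 1)
    dA_more_care <- adult_mortality(rp, trait_allocation(min(1, cc + 0.1), mm),
                                    "S4")
    expect_gte(dA_more_care, dA)
  }
})

test_that("egg mortality decays exponentially with care and validates inputs", {
  expect_equal(egg_mortality(0.5, 0), 0.5)
  expect_equal(egg_mortality(0, 3), 0)
  expect_equal(egg_mortality(0.5, 0.5), 0.5 * exp(-0.5), tolerance = 1e-12)
  expect_lt(egg_mortality(0.7, 0.4), 0.7)
  expect_error(egg_mortality(1.2, 0), "d_E0")
  expect_error(egg_mortality(0.5, -0.1), "'c'")
})

test_that("fertilization success routes preferred traits into the exponent", {
  a <- trait_allocation(c = 0.5, m = 0.5)
  expect_equal(fertilization_success(1, a, "S4"), 1)
  expect_equal(fertilization_success(0.5, a, "S1"), 0.5)
  expect_equal(fertilization_success(0.5, a, "S2"), 1 - 0.5 * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(fertilization_success(0.5, a, "S4"), 1 - 0.5 * exp(-1),
               tolerance = 1e-12)
  # m = 0 reduces S3 to baseline
  expect_equal(fertilization_success(0.5, trait_allocation(c = 0.9, m = 0),
                                     "S3"), 0.5)
  # r always in [r_0, 1]
  set.seed(7)
  for (i in 1:100) {
    r0 <- runif(1)
    r <- fertilization_success(r0, trait_allocation(runif(1), runif(1)), "S4")
    expect_gte(r, r0)
    expect_lte(r, 1)
  }
  expect_error(fertilization_success(-0.1, a, "S1"), "r_0")
})

test_that("per-episode success is r * b * (1 - d_E) and linear in b", {
  expect_equal(episode_reproductive_success(0, 100, 0.3), 0)
  expect_equal(episode_reproductive_success(1, 100, 0), 100)
  expect_equal(episode_reproductive_success(0.5, 100, 0.5 * exp(-0.5)),
               34.83673, tolerance = 1e-6)
  expect_equal(episode_reproductive_success(0.4, 200, 0.2),
               2 * episode_reproductive_success(0.4, 100, 0.2))
  expect_error(episode_reproductive_success(0.5, -1, 0.2), "'b'")
})

test_that("expected future episodes matches the truncated geometric sum", {
  expect_equal(expected_future_episodes(1, 5), 0)
  expect_equal(expected_future_episodes(0.3, 0), 0)

  # brute-force enumeration oracle
  brute <- function(d_A, n) sum((0:n) * d_A * (1 - d_A)^(0:n))
  dA_chain <- 1 - 0.5 * exp(-1)
  expect_equal(expected_future_episodes(dA_chain, 5), brute(dA_chain, 5),
               tolerance = 1e-15)
  expect_equal(expected_future_episodes(dA_chain, 5), 0.2251586,
               tolerance = 1e-6)
  set.seed(11)
  for (i in 1:50) {
    dA <- runif(1); n <- sample(0:12, 1)
    expect_equal(expected_future_episodes(dA, n), brute(dA, n),
                 tolerance = 1e-13)
    if (dA > 0) {
      expect_lte(expected_future_episodes(dA, n), (1 - dA) / dA + 1e-12)
    }
  }
  expect_error(expected_future_episodes(0.5, 2.5), "'n'")
})

test_that("capped lifespan variant adds exactly the censored tail", {
  # E[min(L, n)] for geometric L: truncated sum + n * P(L > n)
  set.seed(13)
  for (i in 1:20) {
    dA <- runif(1, 0.05, 0.95); n <- sample(1:8, 1)
    expect_equal(
      expected_future_episodes(dA, n, capped = TRUE),
      expected_future_episodes(dA, n) + n * (1 - dA)^(n + 1),
      tolerance = 1e-14
    )
  }
})

test_that("lifetime fitness composes R with the future-episode expectation", {
  expect_equal(lifetime_fitness(10, 1, 5), 10)
  expect_equal(lifetime_fitness(0, 0.4, 5), 0)
  expect_equal(lifetime_fitness(34.83673, 1 - 0.5 * exp(-1), 5), 42.68052,
               tolerance = 1e-6)
  expect_error(lifetime_fitness(-1, 0.5, 5), "'R'")
})

test_that("evaluate_fitness reproduces the full hand-evaluated chain", {
  p <- fig_defaults()
  for (id in names(hand_W)) {
    bd <- evaluate_fitness(p, default_allocation(id, "unconstrained"), id)
    expect_equal(bd$W, hand_W[[id]], tolerance = 1e-6)
    expect_equal(bd$R, bd$r * p$b * (1 - bd$d_E), tolerance = 1e-12)
    expect_equal(bd$log_W, log(bd$W))
  }
  # S4 intermediate quantities
  bd4 <- evaluate_fitness(p, default_allocation("S4", "unconstrained"), "S4")
  expect_equal(bd4$r, 1 - 0.5 * exp(-1), tolerance = 1e-12)
  expect_equal(bd4$d_A, 1 - 0.5 * exp(-1.5), tolerance = 1e-12)
})

test_that("zero fitness maps log_W to the -Inf sentinel, not an error", {
  p <- fig_defaults(r_0 = 0, b = 100)
  bd <- evaluate_fitness(p, trait_allocation(0, 0), "S1")
  expect_equal(bd$W, 0)
  expect_identical(bd$log_W, -Inf)
})

test_that("all scenarios collapse to one fitness at zero investment", {
  zero <- trait_allocation(0, 0)
  set.seed(99)
  for (i in 1:200) {
    p <- random_params()
    W <- vapply(c("S1", "S2", "S3", "S4"), function(id) {
      evaluate_fitness(p, zero, id)$W
    }, numeric(1))
    expect_identical(max(W) - min(W), 0)
  }
})

test_that("fitness is exactly linear in b and monotone in r_0 and d_A0", {
  set.seed(5)
  for (i in 1:50) {
    p1 <- random_params()
    alloc <- trait_allocation(runif(1), runif(1))
    for (id in c("S1", "S4")) {
      w1 <- evaluate_fitness(set_b(p1, 1), alloc, id)$W
      wk <- evaluate_fitness(set_b(p1, 137), alloc, id)$W
      expect_equal(wk, 137 * w1, tolerance = 1e-12)
      # increasing in r_0 (strict when b > 0, d_E < 1, r_0 < 1)
      lo <- evaluate_fitness(clone_with(p1, r_0 = 0.2, b = 100), alloc, id)$W
      hi <- evaluate_fitness(clone_with(p1, r_0 = 0.8, b = 100), alloc, id)$W
      expect_gt(hi, lo)
      # nonincreasing in d_A0
      wlo <- evaluate_fitness(clone_with(p1, d_A0 = 0.1), alloc, id)$W
      whi <- evaluate_fitness(clone_with(p1, d_A0 = 0.9), alloc, id)$W
      expect_gte(wlo, whi)
    }
  }
})

test_that("perfect baseline fertilization erases the preference advantage", {
  p <- fig_defaults(r_0 = 1)
  a_care <- trait_allocation(c = 0.5)
  a_both <- trait_allocation(c = 0.5, m = 0.5)
  expect_identical(evaluate_fitness(p, a_care, "S1")$W,
                   evaluate_fitness(p, a_care, "S2")$W)
  expect_identical(evaluate_fitness(p, a_both, "S3")$W,
                   evaluate_fitness(p, a_both, "S4")$W)
  # the trait then carries only its mortality cost
  expect_gte(evaluate_fitness(p, a_care, "S1")$W,
             evaluate_fitness(p, a_both, "S3")$W)
})

test_that("domain errors name the offending field", {
  expect_error(life_history_params(d_E0 = -0.2), "d_E0")
  expect_error(life_history_params(d_A0 = 1.5), "d_A0")
  expect_error(life_history_params(n = -1), "'n'")
  expect_error(trait_allocation(c = 1.4), "'c'")
  expect_error(trait_allocation(m = -0.1), "'m'")
})
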