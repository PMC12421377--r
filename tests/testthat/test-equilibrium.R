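test_that("direct bound fraction matches the single-site quadratic and its limits", {
  # no-depletion limit: FB -> Rt/(Rt+Kd), so Rt = Kd gives half occupancy
  expect_equal(fraction_bound_direct(25, 1e-9, 25), 0.5, tolerance = 1e-6)
  # boundary cases
  expect_equal(fraction_bound_direct(0, 3, 19), 0)
  expect_lt(fraction_bound_direct(30, 3, 1e12), 1e-9)
  # study concentrations, frozen against the bisection oracle
  expect_equal(fraction_bound_direct(30, 3, 19), 0.597521, tolerance = 1e-6)
  r <- oracle_free_receptor(30, 3, 0, 19, 1)
  expect_equal(fraction_bound_direct(30, 3, 19), 3 * r / (19 + r) / 3,
               tolerance = 1e-9)
  # monotone and continuous in receptor concentration
  fb <- fraction_bound_direct(seq(0, 300, by = 0.5), 3, 19)
  expect_true(all(diff(fb) > 0))
  expect_true(all(fb >= 0 & fb <= 1))
})

test_that("invalid equilibrium inputs are rejected", {
  expect_error(fraction_bound_direct(-1, 3, 19), "require")
  expect_error(fraction_bound_direct(30, 3, 0), "require")
  expect_error(fraction_bound_direct(Inf, 3, 19), "finite")
  expect_error(eq_system(30, 3, -1, kd_probe = 19), ">= 0")
  expect_error(eq_system(30, 3, 0, kd_probe = 0), "> 0")
  expect_error(eq_system(NA, 3, 0, kd_probe = 19), "finite")
})

test_that("competitive solution reduces to the direct model and to total competition", {
  # It = 0: probe fraction equals the direct quadratic, for any competitor Kd
  for (k2 in c(0.1, 40, 1e4)) {
    s <- eq_system(30, 3, 0, kd_probe = 19, kd_competitor = k2)
    expect_equal(solve_competitive(s)$fraction_probe_bound,
                 fraction_bound_direct(30, 3, 19), tolerance = 1e-9)
  }
  # It -> infinity: probe displaced entirely
  s <- eq_system(30, 3, 1e9, kd_probe = 19, kd_competitor = 40)
  expect_lt(solve_competitive(s)$fraction_probe_bound, 1e-6)
  # frozen value at the study concentrations (bisection oracle)
  s <- eq_system(30, 3, 1000, kd_probe = 19, kd_competitor = 40)
  expect_equal(solve_competitive(s)$fraction_probe_bound, 0.0584547,
               tolerance = 1e-6)
})

test_that("analytic root agrees with the bisection oracle on random systems", {
  set.seed(101)
  n <- 2000
  rt <- 10^stats::runif(n, -3, 6)
  lt <- 10^stats::runif(n, -3, 6)
  it <- 10^stats::runif(n, -3, 6)
  k1 <- 10^stats::runif(n, -2, 5)
  k2 <- 10^stats::runif(n, -2, 5)
  for (i in seq_len(n)) {
    s <- eq_system(rt[i], lt[i], it[i], kd_probe = k1[i], kd_competitor = k2[i])
    # degenerate coefficient sets legitimately warn and fall back to bisection
    a <- suppressWarnings(solve_competitive(s))$fraction_probe_bound
    o <- numeric_equilibrium(s)$fraction_probe_bound
    expect_lt(abs(a - o) / max(o, 1e-6), 1e-9)
  }
})

test_that("equilibrium solutions conserve mass and respect monotonicity", {
  set.seed(202)
  for (i in 1:200) {
    rt <- 10^stats::runif(1, -1, 3); lt <- 10^stats::runif(1, -1, 2)
    it <- 10^stats::runif(1, -1, 4)
    k1 <- 10^stats::runif(1, -1, 3); k2 <- 10^stats::runif(1, -1, 3)
    s <- eq_system(rt, lt, it, kd_probe = k1, kd_competitor = k2)
    sol <- solve_competitive(s)
    r <- sol$receptor_free
    expect_gte(r, 0); expect_lte(r, rt)
    # mass balance: free + probe-bound + competitor-bound receptor = total
    expect_lt(abs(r + lt * sol$fraction_probe_bound +
                    it * sol$fraction_competitor_bound - rt), 1e-9 * max(1, rt))
    # more competitor or weaker probe binding lowers the probe-bound fraction
    up_it <- solve_competitive(eq_system(rt, lt, it * 3, kd_probe = k1,
                                         kd_competitor = k2))
    expect_lte(up_it$fraction_probe_bound, sol$fraction_probe_bound + 1e-12)
    up_k1 <- solve_competitive(eq_system(rt, lt, it, kd_probe = k1 * 3,
                                         kd_competitor = k2))
    expect_lte(up_k1$fraction_probe_bound, sol$fraction_probe_bound + 1e-12)
    # more receptor or a weaker competitor raises it
    up_rt <- solve_competitive(eq_system(rt * 3, lt, it, kd_probe = k1,
                                         kd_competitor = k2))
    expect_gte(up_rt$fraction_probe_bound, sol$fraction_probe_bound - 1e-12)
    up_k2 <- solve_competitive(eq_system(rt, lt, it, kd_probe = k1,
                                         kd_competitor = k2 * 3))
    expect_gte(up_k2$fraction_probe_bound, sol$fraction_probe_bound - 1e-12)
  }
})

test_that("probe and competitor roles are symmetric", {
  set.seed(303)
  for (i in 1:50) {
    rt <- 10^stats::runif(1, -1, 3)
    lt <- 10^stats::runif(1, -1, 2); it <- 10^stats::runif(1, -1, 2)
    k1 <- 10^stats::runif(1, -1, 3); k2 <- 10^stats::runif(1, -1, 3)
    a <- solve_competitive(eq_system(rt, lt, it, kd_probe = k1,
                                     kd_competitor = k2))
    b <- solve_competitive(eq_system(rt, it, lt, kd_probe = k2,
                                     kd_competitor = k1))
    expect_equal(a$fraction_probe_bound, b$fraction_competitor_bound,
                 tolerance = 1e-9)
    expect_equal(a$fraction_competitor_bound, b$fraction_probe_bound,
                 tolerance = 1e-9)
  }
})

test_that("degenerate systems fall through to the bisection solver", {
  # Rt = 0 leaves no free receptor and nothing bound
  s <- eq_system(0, 3, 10, kd_probe = 19, kd_competitor = 40)
  sol <- numeric_equilibrium(s)
  expect_equal(sol$receptor_free, 0)
  expect_equal(sol$fraction_probe_bound, 0)
  expect_equal(sol$fraction_competitor_bound, 0)
})
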