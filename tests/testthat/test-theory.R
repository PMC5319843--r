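test_that("lambert_w0 satisfies its defining identity across the domain", {
  xs <- c(-exp(-1) + 1e-12, -0.367, -0.3, -2 * exp(-2), -0.05, 0, 0.5, 1,
          exp(1), 10, 1e4)
  for (x in xs) {
    w <- lambert_w0(x)
    expect_gte(w, -1)
    expect_lte(abs(w * exp(w) - x), 1e-12 * (1 + abs(x)))
  }
  expect_identical(lambert_w0(0), 0)
  expect_equal(lambert_w0(exp(1)), 1, tolerance = 1e-12)
  # against an independent bisection oracle
  expect_equal(lambert_w0(-2 * exp(-2)), w_bisect(-2 * exp(-2)),
               tolerance = 1e-10)
  expect_equal(lambert_w0(-2 * exp(-2)), -0.40637573995996, tolerance = 1e-10)
  expect_error(lambert_w0(-0.5), "domain")
})

test_that("the critical-level map matches the bisection oracle and its stated limits", {
  # frozen from the independent oracle: B - (1-B) * w_bisect(z e^z), z = B/(1-B)
  expect_equal(allee_from_critical(2), 1.59362426004004, tolerance = 1e-9)

  Bs <- c(1.001, 1.01, 1.1, 1.5, 2, 3, 5, 10, 50)
  As <- allee_from_critical(Bs)
  expect_true(all(As > 1 & As <= Bs))        # A <= B, as expected
  expect_true(all(diff(As) > 0))             # monotone increasing
  expect_true(all(As < 2))                   # bounded above by 2
  expect_lt(abs(allee_from_critical(1.0001) - 1.0001), 1e-6)  # A -> 1 with B
})

test_that("inverting the critical-level map round-trips to 1e-8", {
  for (B in c(1.001, 1.01, 1.1, 1.7, 2.5, 4, 7, 9.9)) {
    A <- allee_from_critical(B)
    expect_equal(critical_from_allee(A), B, tolerance = 1e-8)
    expect_lte(abs(allee_from_critical(critical_from_allee(A)) - A), 1e-8)
  }
  expect_equal(critical_from_allee(1.59362426004004), 2, tolerance = 1e-7)
  expect_error(critical_from_allee(1), "A")
  expect_error(critical_from_allee(0.5), "A")
  expect_error(critical_from_allee(2.5), "no finite critical level")
})

test_that("the lower switching-level bound dominates the critical level", {
  expect_equal(l1_lower_bound(2), 2 * exp(2) / (exp(2) - 1), tolerance = 1e-12)
  expect_equal(l1_lower_bound(1.0001), exp(1) / (exp(1) - 1), tolerance = 1e-3)
  for (B in c(1.001, 1.5, 2, 5, 10)) expect_gt(l1_lower_bound(B), B)
  expect_lt(l1_lower_bound(30) / 30, 1 + 1e-10)   # ratio -> 1 for large B
  # ordering chain A <= B < L1_min
  for (A in c(1.001, 1.3, 1.8)) {
    B <- critical_from_allee(A)
    expect_lte(A, B + 1e-9)
    expect_lt(B, l1_lower_bound(B))
  }
})

test_that("the upper switching-level bound behaves as derived", {
  B <- critical_from_allee(1.001)
  # equality case: at L1 exactly on its lower bound the log term vanishes
  L1c <- l1_lower_bound(B)
  expect_equal(l2_upper_bound(L1c, B, r1 = 1), L1c, tolerance = 1e-8)
  # 1/r1 scaling of the admissible gap
  g1 <- l2_upper_bound(3, B, r1 = 1) - 3
  g2 <- l2_upper_bound(3, B, r1 = 2) - 3
  expect_equal(g1 / g2, 2, tolerance = 1e-10)
  # the bound separates the surviving (L2 = 4) and extinct (L2 = 4.5)
  # members of the shipped threshold pair
  bd <- l2_upper_bound(3, B, r1 = 1)
  expect_gt(bd, 4)
  expect_lt(bd, 4.5)
  # no admissible L2 when L1 + W0(-L1 e^-L1) collapses to zero
  expect_warning(res <- l2_upper_bound(1, B, r1 = 1), "no admissible")
  expect_true(is.na(res))
})

test_that("pure colonialism is classified by the Allee capacity alone", {
  expect_identical(colonial_outcome(1.001), "extinction_guaranteed")
  expect_identical(colonial_outcome(2), "extinction_guaranteed")
  expect_identical(colonial_outcome(0.5), "survival_possible")
  expect_error(colonial_outcome(1), "boundary")
})

test_that("theory_bounds aggregates the derived quantities coherently", {
  tb <- theory_bounds(1.001, L1 = 3, r1 = 1)
  expect_s3_class(tb, "nc_theory_bounds")
  expect_equal(tb$B, critical_from_allee(1.001), tolerance = 1e-10)
  expect_gt(tb$L1_min, tb$B)
  expect_gt(tb$L2_max, 3)
  expect_error(theory_bounds(1.001, L1 = 3), "r1")
})
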