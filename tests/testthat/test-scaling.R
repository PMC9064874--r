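test_that("exposure factor has the correct limits and quadrature value", {
  r <- seq(0, 10, by = 0.05)
  rho <- exp(-r)
  expect_equal(exposure_m(r, rho, rep(1, length(r))), 1)
  expect_equal(exposure_m(r, rho, rep(0.5, length(r))), 0.5)

  # against an independent quadrature with a non-trivial weight profile
  f <- 1 / (1 + r)
  num <- stats::integrate(function(x) exp(-x) * x^2 / (1 + x), 0, 10,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(function(x) exp(-x) * x^2, 0, 10,
                          rel.tol = 1e-12)$value
  expect_equal(exposure_m(r, rho, f), num / den, tolerance = 1e-4)

  expect_error(exposure_m(r, rho * 0, f), "invalid-profile")
  expect_error(exposure_m(r, rho[-1], f), "invalid-profile")
})

test_that("m-scaled unscreened polarizability hits its stated limits", {
  ref <- get_reference("C", ref_table)
  base <- tibble::tibble(element = "C", x = 0, y = 0, z = 0, n = 6, q = 0,
                         r3 = ref$r3_ref, r4 = ref$r4_ref, volume = 100,
                         m = 1, rdamp = ref$rdamp_ref)
  # AIM moments equal to the reference, m = 1: exactly the reference value
  expect_equal(unscreened_alpha(base, ref), ref$alpha_ref, tolerance = 1e-12)

  # m = 0: the buried-atom volume law alpha = C * <r3>
  buried <- dplyr::mutate(base, m = 0, r3 = 10)
  expect_equal(unscreened_alpha(buried, ref), 4.0)

  # m = 0.5: geometric mean of the two laws
  half <- dplyr::mutate(base, m = 0.5, r3 = 30, r4 = 150, n = 5.7)
  cf <- scaling_coefficients()[1, ]
  omega <- ref$alpha_ref * (5.7 / 6)^cf$n_exponent *
    (30 / ref$r3_ref)^cf$r3_exponent * (150 / ref$r4_ref)^cf$r4_exponent
  expect_equal(unscreened_alpha(half, ref), sqrt(0.4 * 30 * omega),
               tolerance = 1e-12)
})

test_that("m-scaled wp reduces to the isolated-atom law and stays positive", {
  ref <- get_reference("O", ref_table)
  iso <- tibble::tibble(element = "O", n = 8.4, q = -0.4, x = 0, y = 0, z = 0,
                        r3 = 1.2 * ref$r3_ref, r4 = 1.1 * ref$r4_ref,
                        volume = 50, m = 1, rdamp = ref$rdamp_ref)
  cf <- scaling_coefficients()[3, ]
  direct <- ref$wp_ref * (8.4 / 8)^cf$n_exponent * 1.2^cf$r3_exponent *
    1.1^cf$r4_exponent
  expect_equal(unscreened_wp(iso, ref), direct, tolerance = 1e-12)

  for (m in c(0, 0.3, 0.7, 1)) {
    expect_gt(unscreened_wp(dplyr::mutate(iso, m = m), ref), 0)
  }
})

test_that("the full unscreened pipeline returns the reference triple exactly", {
  toy <- make_toy_system("single_atom", element = "Kr", reference = ref_table)
  st <- unscreened_state(toy$atoms, ref_table)
  ref <- get_reference("Kr", ref_table)
  expect_equal(st$alpha_unscreened, ref$alpha_ref, tolerance = 1e-10)
  expect_equal(st$wp, ref$wp_ref, tolerance = 1e-10)
  expect_equal(st$c6_unscreened, ref$c6_ref, tolerance = 1e-10)
})

test_that("conduction upper bound is linear in volume with the plate ratio", {
  expect_equal(conduction_upper_bound(2) / conduction_upper_bound(1), 2)
  v <- c(0.3, 7, 120)
  expect_equal(conduction_upper_bound(v) / v, rep(1 / (2 * pi), 3))
  expect_error(conduction_upper_bound(0), "invalid-value")
})

test_that("smooth minimum honours the zero rule and the deviation band", {
  expect_equal(smooth_min(-1, 5), 0)
  expect_equal(smooth_min(5, 0), 0)
  expect_equal(smooth_min(1, 1), 1, tolerance = 0.0058)

  # dense positive scan: relative deviation from min(a, b) within 0.58%
  g <- exp(seq(log(0.01), log(100), length.out = 120))
  dev <- outer(g, g, function(a, b) abs(smooth_min(a, b) - pmin(a, b)) / pmin(a, b))
  expect_lte(max(dev), 0.0058)

  # first-derivative continuity in a for a, b > 0 (symmetric crossing)
  h <- 1e-6
  d1 <- (smooth_min(1 + h, 1) - smooth_min(1 - h, 1)) / (2 * h)
  expect_lt(abs(d1 - 0.5), 1e-3)  # symmetric smooth crossing slope
})

test_that("aim_atoms enforces the electron-count invariant", {
  toy <- make_toy_system("dimer", element = "Ne", reference = ref_table)$atoms
  bad <- dplyr::mutate(toy, n = n + 0.1)
  expect_error(aim_atoms(bad), "consistency-error")
  expect_error(aim_atoms(dplyr::mutate(toy, m = 1.2)), "invalid-value")
})
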