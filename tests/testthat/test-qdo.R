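test_that("atomic C8 follows the fitted correlation and is monotone in C6", {
  c6 <- 40; r3 <- 30; r4 <- 140
  expect_equal(c8_atom(c6, r3, r4),
               exp(1.7327) * c6 * (r4 / r3)^0.8305)
  expect_gt(c8_atom(2 * c6, r3, r4), c8_atom(c6, r3, r4))
  expect_error(c8_atom(-1, r3, r4), "invalid-value")
})

test_that("QDO parameterization round-trips alpha, C6 and C8", {
  set.seed(13)
  for (i in 1:100) {
    alpha <- stats::runif(1, 0.5, 200)
    wp <- stats::runif(1, 0.05, 1.5)
    m <- stats::runif(1, 0.2, 5)
    c6 <- 0.75 * alpha^2 * wp
    c8 <- 7.5 * alpha^2 / m
    p <- qdo_parameterize(alpha, c6, c8)
    expect_equal(p$wp_qdo, wp, tolerance = 1e-10)
    expect_equal(p$m_qdo, m, tolerance = 1e-10)
    expect_gt(p$q_qdo, 0)
    # regenerate the inputs from the parameters
    expect_equal(0.75 * alpha^2 * p$wp_qdo, c6, tolerance = 1e-10)
    expect_equal(7.5 * alpha^2 / p$m_qdo, c8, tolerance = 1e-10)
    expect_equal(p$q_qdo^2 / (p$m_qdo * p$wp_qdo^2), alpha, tolerance = 1e-10)
  }
  # alpha -> k alpha with C6 -> k^2 C6 at fixed wp leaves wp_qdo unchanged
  p1 <- qdo_parameterize(10, 0.75 * 100 * 0.4, 500)
  p2 <- qdo_parameterize(30, 0.75 * 900 * 0.4, 4500)
  expect_equal(p1$wp_qdo, p2$wp_qdo, tolerance = 1e-12)
})

test_that("higher-order mixing rules reduce on the diagonal and are symmetric", {
  params <- tibble::tibble(
    wp_qdo = c(0.4, 0.9, 0.15), m_qdo = c(1.2, 0.6, 3),
    q_qdo = 1, alpha_ff = c(12, 5, 60)
  )
  ho <- higher_order_coefficients(params, pairs = TRUE, triples = TRUE)
  expect_equal(diag(ho$c8_ab), ho$atom$c8)
  expect_equal(diag(ho$c10_ab), ho$atom$c10)
  expect_equal(ho$c8_ab, t(ho$c8_ab))
  expect_equal(ho$c10_ab, t(ho$c10_ab))
  expect_true(all(ho$atom$c8 > 0 & ho$atom$c9 > 0 & ho$atom$c10 > 0))
  # C9 symmetric under any permutation of the three atoms
  expect_equal(ho$c9_abc[1, 2, 3], ho$c9_abc[3, 1, 2])
  expect_equal(ho$c9_abc[1, 2, 3], ho$c9_abc[2, 1, 3])
  # homoatomic closed forms
  wp <- params$wp_qdo[1]; a1 <- params$alpha_ff[1]
  a2 <- ho$atom$alpha2[1]; a3 <- ho$atom$alpha3[1]
  expect_equal(ho$atom$c8[1], 5 * wp * a1 * a2, tolerance = 1e-12)
  expect_equal(ho$atom$c10[1], 17.5 * wp * a2^2 + 10.5 * wp * a1 * a3,
               tolerance = 1e-12)
  expect_equal(ho$atom$c9[1], (9 / 16) * wp * a1^3, tolerance = 1e-12)
})

test_that("pair coefficients agree with direct Casimir-Polder quadrature", {
  # independent oracle: integrate the multi-Lorentzian multipole
  # polarizabilities numerically and assemble C8_AB / C10_AB / C9_ABC from
  # the standard multipole-expansion prefactors
  params <- tibble::tibble(
    wp_qdo = c(0.35, 0.8), m_qdo = c(1.1, 0.7), q_qdo = 1,
    alpha_ff = c(15, 4)
  )
  ho <- higher_order_coefficients(params, pairs = TRUE, triples = TRUE)
  al <- function(i, l) {
    dfact <- c(1, 3, 15)[l]
    params$alpha_ff[i] * (dfact / (2 * params$m_qdo[i] * params$wp_qdo[i]))^(l - 1)
  }
  lor <- function(i, l, w) al(i, l) / (1 + (w / (l * params$wp_qdo[i]))^2)
  G <- function(i, li, j, lj) {
    (1 / pi) * stats::integrate(function(w) lor(i, li, w) * lor(j, lj, w),
                                0, Inf, rel.tol = 1e-12)$value
  }
  c8_12 <- 7.5 * (G(1, 1, 2, 2) + G(1, 2, 2, 1))
  expect_equal(ho$c8_ab[1, 2], c8_12, tolerance = 1e-8)
  c10_12 <- 35 * G(1, 2, 2, 2) + 14 * (G(1, 1, 2, 3) + G(1, 3, 2, 1))
  expect_equal(ho$c10_ab[1, 2], c10_12, tolerance = 1e-8)
  # triple-dipole coefficient vs the known closed form of the
  # three-Lorentzian integral
  w1 <- params$wp_qdo[1]; w2 <- params$wp_qdo[2]
  trip <- (3 / pi) * stats::integrate(function(w) {
    lor(1, 1, w) * lor(1, 1, w) * lor(2, 1, w)
  }, 0, Inf, rel.tol = 1e-12)$value
  expect_equal(ho$c9_abc[1, 1, 2], trip, tolerance = 1e-8)
})

test_that("the three-body energy term evaluates the printed formula", {
  # equilateral triangle: 1 + 3 (1/2)^3 = 11/8
  R <- 6
  expect_equal(e9_term(100, R, R, R), 100 * (11 / 8) / R^9)
  # right triangle: the cos 90 factor kills the angular product
  r_ab <- 3; r_ac <- 4; r_bc <- 5  # right angle at A
  expect_equal(e9_term(50, r_ab, r_ac, r_bc),
               50 / (r_ab * r_ac * r_bc)^3)
  # random triangle vs direct evaluation with explicitly supplied angles
  a <- 4; b <- 6; c <- 7.5
  cos_a <- (a^2 + b^2 - c^2) / (2 * a * b)
  cos_b <- (a^2 + c^2 - b^2) / (2 * a * c)
  cos_c <- (b^2 + c^2 - a^2) / (2 * b * c)
  expect_equal(e9_term(10, a, b, c),
               e9_term(10, a, b, c,
                       angles = acos(c(cos_a, cos_b, cos_c))))
  expect_error(e9_term(1, 1, 1, 3), "invalid-triangle")
})
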