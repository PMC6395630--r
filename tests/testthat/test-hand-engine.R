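test_that("combined sensitivity is the mixture-weighted sum with zero-extension", {
  pair <- curve_pair(hill_curve(0, 0.8, 1, 2), hill_curve(0, 1, 1.5, 1.3))
  x <- seq(0.05, 0.75, by = 0.1)
  expect_equal(combined_sensitivity(pair, 1, x),
               hill_sensitivity(pair$curve_a, x))
  sham <- curve_pair(hill_curve(0, 1, 2, 1.5), hill_curve(0, 1, 2, 1.5))
  expect_equal(combined_sensitivity(sham, 0.5, x),
               hill_sensitivity(sham$curve_a, x))
  # above the partial agent's e_max only the full agent contributes
  expect_equal(combined_sensitivity(pair, 0.25, 0.9),
               0.75 * hill_sensitivity(pair$curve_b, 0.9))
})

test_that("hand_inverse collapses to the single-agent inverse at the ratio endpoints", {
  set.seed(41)
  pair <- random_full_pair()
  x <- 0.55
  expect_equal(hand_inverse(pair, 1, x), hill_inverse(pair$curve_a, x),
               tolerance = 1e-9)
  expect_equal(hand_inverse(pair, 0, x), hill_inverse(pair$curve_b, x),
               tolerance = 1e-9)
  sham <- curve_pair(hill_curve(0, 1, 2, 1.5), hill_curve(0, 1, 2, 1.5))
  expect_equal(hand_inverse(sham, 0.3, 0.5), hill_inverse(sham$curve_a, 0.5),
               tolerance = 1e-7)
})

test_that("hand_inverse matches the constant-potency closed form along rays", {
  set.seed(42)
  for (i in 1:5) {
    pair <- random_constant_potency_pair()
    alpha <- pair$curve_a$ec50 / pair$curve_b$ec50
    lambda <- runif(1, 0.1, 0.9)
    x <- runif(1, 0.2, 0.8)
    # E(a,b) = f_A(a + alpha b) inverted along a = lambda c, b = (1-lambda) c
    expected <- hill_inverse(pair$curve_a, x) / (lambda + alpha * (1 - lambda))
    expect_equal(hand_inverse(pair, lambda, x), expected, tolerance = 1e-6)
  }
})

test_that("hand combined curve inverts hand_inverse and is continuous at c_star", {
  pair <- curve_pair(hill_curve(0, 1, 1, 1), hill_curve(0, 1, 3, 2))
  for (x in c(0.2, 0.5, 0.85)) {
    cc <- hand_inverse(pair, 0.4, x)
    expect_equal(hand_combined_curve(pair, 0.4, cc), x, tolerance = 1e-8)
  }
  expect_equal(hand_combined_curve(pair, 1, 1), 0.5) # EC50 of A

  pp <- curve_pair(hill_curve(0, 0.8, 1, 2), hill_curve(0, 1, 1, 2))
  cs <- c_star(pp, 0.5)
  lo <- hand_combined_curve(pp, 0.5, cs * (1 - 1e-7))
  hi <- hand_combined_curve(pp, 0.5, cs * (1 + 1e-7))
  expect_equal(lo, 0.8, tolerance = 1e-5)
  expect_equal(hi, 0.8, tolerance = 1e-5)
  expect_gte(hi, lo - 1e-9)
})

test_that("c_star reduces to f_B^{-1}(e_max_A) at lambda 0, matches a dense trapezoid oracle, grows with lambda", {
  pp <- curve_pair(hill_curve(0, 0.8, 1, 2), hill_curve(0, 1, 1, 2))
  expect_equal(c_star(pp, 0), hill_inverse(pp$curve_b, 0.8), tolerance = 1e-8)

  # independent oracle: trapezoid on the effect-space integrand with the
  # square-root substitution x = e_max_A * u^2 defusing the baseline
  # singularity
  lam <- 0.5
  u <- seq(0, 1, length.out = 200001)[-1]
  x <- 0.8 * u^2
  integrand <- (2 * 0.8 * u) /
    (lam * hill_sensitivity(pp$curve_a, x) +
       (1 - lam) * hill_sensitivity(pp$curve_b, x))
  oracle <- sum((integrand[-1] + integrand[-length(integrand)]) / 2 * diff(u))
  expect_equal(c_star(pp, 0.5), oracle, tolerance = 1e-4)

  cs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(l) c_star(pp, l),
               numeric(1))
  expect_true(all(diff(cs) > 0))
  expect_identical(c_star(pp, 1), Inf)
  expect_error(c_star(curve_pair(hill_curve(0, 1, 1, 1),
                                 hill_curve(0, 1, 2, 2)), 0.5),
               "partial agent")
})

test_that("the limit isobole decreases to zero B-dose as lambda approaches 1", {
  pp <- curve_pair(hill_curve(0, 0.8, 1, 2), hill_curve(0, 1, 1.5, 1.5))
  li <- limit_isobole(pp, c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 0.99, 0.9999))
  expect_equal(li$b_star[1], hill_inverse(pp$curve_b, 0.8), tolerance = 1e-7)
  expect_equal(li$a_star[1], 0)
  expect_true(all(diff(li$b_star) < 0))
  expect_lt(li$b_star[8], 0.01)
  expect_equal(li$a_star + li$b_star, li$c_star, tolerance = 1e-12)
})

test_that("N = 1 alternating scheme reproduces the Tallarida closed form exactly", {
  set.seed(43)
  for (i in 1:5) {
    pair <- random_full_pair()
    a <- random_dose(pair$curve_a)
    b <- random_dose(pair$curve_b)
    expect_equal(tallarida_iterated(pair, a, b, 1, "a_first"),
                 tallarida_effect(pair, a, b, "a_to_b"), tolerance = 1e-13)
    expect_equal(tallarida_iterated(pair, a, b, 1, "b_first"),
                 tallarida_effect(pair, a, b, "b_to_a"), tolerance = 1e-13)
  }
})

test_that("the sham combination telescopes exactly for any N and order", {
  crv <- hill_curve(0, 1, 2, 1.5)
  sham <- curve_pair(crv, crv)
  for (n in c(1, 3, 16)) {
    expect_equal(tallarida_iterated(sham, 1, 2, n, "a_first"),
                 hill_eval(crv, 3), tolerance = 1e-10)
    expect_equal(tallarida_iterated(sham, 1, 2, n, "b_first"),
                 hill_eval(crv, 3), tolerance = 1e-10)
  }
})

test_that("the alternating scheme converges to the Hand model with vanishing order dependence", {
  set.seed(44)
  ns <- c(4, 16, 64, 256, 1024)
  for (i in 1:3) {
    pair <- random_pair()
    a <- random_dose(pair$curve_a)
    b <- random_dose(pair$curve_b)
    target <- hand_effect(pair, a, b)
    err_a <- vapply(ns, function(n)
      abs(tallarida_iterated(pair, a, b, n, "a_first") - target), numeric(1))
    err_b <- vapply(ns, function(n)
      abs(tallarida_iterated(pair, a, b, n, "b_first") - target), numeric(1))
    expect_lt(err_a[length(ns)], 1e-3)
    expect_lt(err_b[length(ns)], 1e-3)
    gap <- vapply(ns, function(n)
      abs(tallarida_iterated(pair, a, b, n, "a_first") -
            tallarida_iterated(pair, a, b, n, "b_first")), numeric(1))
    expect_lt(gap[length(ns)], gap[1] + 1e-12)
  }
})

test_that("hand bounds loewe from above wherever loewe is defined", {
  set.seed(45)
  for (i in 1:10) {
    pair <- random_pair()
    a <- random_dose(pair$curve_a)
    b <- random_dose(pair$curve_b)
    lw <- tryCatch(loewe_effect(pair, a, b),
                   combonull_loewe_undefined = function(c) NA)
    if (is.na(lw)) next
    expect_gte(hand_effect(pair, a, b), lw - 1e-6)
  }
})
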