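test_that("curve pairs require a shared baseline and label the partial agent", {
  expect_error(curve_pair(hill_curve(0, 1, 1, 1), hill_curve(0.2, 1, 1, 1)),
               "baseline")
  p <- curve_pair(hill_curve(0, 0.8, 1, 2), hill_curve(0, 1, 1, 2))
  expect_false(p$equal_e_max)
  expect_identical(p$partial, "a")
  expect_identical(swap_pair(p)$partial, "b")
  q <- curve_pair(hill_curve(0, 1, 1, 1), hill_curve(0, 1, 3, 2))
  expect_true(q$equal_e_max)
})

test_that("Loewe solves the additivity equation and respects sham and axes", {
  pair <- curve_pair(hill_curve(0, 1, 1.0, 1.0), hill_curve(0, 1, 3.0, 2.0))
  a <- hill_inverse(pair$curve_a, 0.5) / 3
  b <- 2 * hill_inverse(pair$curve_b, 0.5) / 3
  expect_equal(loewe_effect(pair, a, b), 0.5, tolerance = 1e-8)

  sham <- curve_pair(hill_curve(0, 1, 2, 1.5), hill_curve(0, 1, 2, 1.5))
  x <- 0.62
  half <- hill_inverse(sham$curve_a, x) / 2
  expect_equal(loewe_effect(sham, half, half), x, tolerance = 1e-8)

  expect_equal(loewe_effect(pair, 1.7, 0), hill_eval(pair$curve_a, 1.7),
               tolerance = 1e-8)
  expect_equal(loewe_effect(pair, 0, 0), 0)
})

test_that("Loewe reduces to the constant-potency closed form", {
  set.seed(31)
  for (i in 1:10) {
    pair <- random_constant_potency_pair()
    alpha <- pair$curve_a$ec50 / pair$curve_b$ec50
    a <- random_dose(pair$curve_a)
    b <- random_dose(pair$curve_b)
    expect_equal(loewe_effect(pair, a, b),
                 hill_eval(pair$curve_a, a + alpha * b), tolerance = 1e-6)
  }
})

test_that("Loewe is undefined beyond the partial agent's range, with HSA extension continuous", {
  pair <- curve_pair(hill_curve(0, 0.8, 1, 2), hill_curve(0, 1, 1, 2))
  b_lim <- hill_inverse(pair$curve_b, 0.8)
  expect_error(loewe_effect(pair, 0.5, b_lim * 1.01),
               class = "combonull_loewe_undefined")
  cnd <- tryCatch(loewe_effect(pair, 0.5, b_lim * 1.01),
                  combonull_loewe_undefined = function(c) c)
  expect_equal(cnd$limit, 0.8)
  # defined just below the horizontal limit isobole
  expect_lt(loewe_effect(pair, 0.5, b_lim * 0.999), 0.8)
  # HSA extension: equals Loewe below, HSA above, continuous across
  expect_equal(loewe_hsa_effect(pair, 0.5, b_lim * 0.5),
               loewe_effect(pair, 0.5, b_lim * 0.5))
  expect_equal(loewe_hsa_effect(pair, 0.5, b_lim * 2),
               hsa_effect(pair, 0.5, b_lim * 2))
  below <- loewe_hsa_effect(pair, 3, b_lim * (1 - 1e-7))
  above <- loewe_hsa_effect(pair, 3, b_lim * (1 + 1e-7))
  expect_equal(below, 0.8, tolerance = 1e-5)
  expect_equal(above, 0.8, tolerance = 1e-5)
})

test_that("Tallarida orderings match hand-computed equivalent-dose values", {
  pair <- curve_pair(hill_curve(0, 1, 1, 1), hill_curve(0, 1, 1, 2))
  # A->B: f_A(1) = 0.5, B-equivalent 1, f_B(2) = 0.8
  expect_equal(tallarida_effect(pair, 1, 1, "a_to_b"), 0.8, tolerance = 1e-12)
  # B->A: f_B(1) = 0.5, A-equivalent 1, f_A(2) = 2/3
  expect_equal(tallarida_effect(pair, 1, 1, "b_to_a"), 2 / 3,
               tolerance = 1e-12)
  env <- tallarida_envelope(pair, 1, 1)
  expect_equal(c(env$lb, env$ub), c(2 / 3, 0.8), tolerance = 1e-12)
  expect_true(env$both_defined)
  # axes
  expect_equal(tallarida_effect(pair, 0, 1.3, "a_to_b"),
               hill_eval(pair$curve_b, 1.3))
  env0 <- tallarida_envelope(pair, 1.3, 0)
  expect_equal(env0$lb, env0$ub)
  expect_equal(env0$lb, hill_eval(pair$curve_a, 1.3))
})

test_that("Tallarida sham reduces to f_A(a + b) and saturation raises a named condition", {
  crv <- hill_curve(0, 1, 2, 1.5)
  sham <- curve_pair(crv, crv)
  expect_equal(tallarida_effect(sham, 1, 2, "a_to_b"), hill_eval(crv, 3),
               tolerance = 1e-12)
  expect_equal(tallarida_effect(sham, 1, 2, "b_to_a"), hill_eval(crv, 3),
               tolerance = 1e-12)
  # full agent A pushes past partial B's maximal effect
  pair <- curve_pair(hill_curve(0, 1, 1, 2), hill_curve(0, 0.6, 1, 2))
  a_big <- hill_inverse(pair$curve_a, 0.7)
  expect_error(tallarida_effect(pair, a_big, 0.1, "a_to_b"),
               class = "combonull_equivalent_dose_undefined")
  env <- tallarida_envelope(pair, a_big, 0.1)
  expect_false(env$both_defined)
  expect_equal(env$lb, env$ub)
})

test_that("Bliss follows the probabilistic formula and enforces the unit scale", {
  pair <- curve_pair(hill_curve(0, 1, 1, 1), hill_curve(0, 1, 2, 2))
  a <- hill_inverse(pair$curve_a, 0.5)
  b <- hill_inverse(pair$curve_b, 0.5)
  expect_equal(bliss_effect(pair, a, b), 0.75, tolerance = 1e-12)
  expect_equal(bliss_effect(pair, 0, b), 0.5, tolerance = 1e-12)
  raw <- curve_pair(hill_curve(0, 2, 1, 1), hill_curve(0, 2, 2, 2))
  expect_error(bliss_effect(raw, 1, 1), class = "combonull_not_normalised")
  expect_equal(bliss_effect(raw, 0, 0, normalise = TRUE), 0)
})

test_that("HSA takes the better monotherapy and violates sham", {
  pair <- curve_pair(hill_curve(0, 1, 1, 1), hill_curve(0, 1, 2, 2))
  a <- hill_inverse(pair$curve_a, 0.3)
  b <- hill_inverse(pair$curve_b, 0.6)
  expect_equal(hsa_effect(pair, a, b), 0.6, tolerance = 1e-9)
  expect_equal(hsa_effect(pair, 0, 0), 0)
  crv <- hill_curve(0, 1, 2, 1.5)
  sham <- curve_pair(crv, crv)
  expect_lt(hsa_effect(sham, 1, 1), hill_eval(crv, 2)) # sham violated
})

test_that("all models agree with the monotherapies on the axes", {
  set.seed(32)
  pair <- random_full_pair()
  for (model in c("loewe", "loewe_hsa", "tallarida_ab", "tallarida_ba",
                  "tallarida_lb", "tallarida_ub", "hand", "bliss", "hsa")) {
    s <- null_surface(model, pair)
    a <- random_dose(pair$curve_a)
    b <- random_dose(pair$curve_b)
    expect_equal(surface_effect(s, a, 0), hill_eval(pair$curve_a, a),
                 tolerance = 1e-7, label = paste(model, "A axis"))
    expect_equal(surface_effect(s, 0, b), hill_eval(pair$curve_b, b),
                 tolerance = 1e-7, label = paste(model, "B axis"))
  }
})

test_that("loewe, hand, bliss, hsa are commutative; tallarida orderings swap", {
  set.seed(33)
  for (i in 1:5) {
    pair <- random_pair()
    swapped <- swap_pair(pair)
    a <- random_dose(pair$curve_a)
    b <- random_dose(pair$curve_b)
    lw <- tryCatch(loewe_effect(pair, a, b),
                   combonull_loewe_undefined = function(c) NA)
    if (!is.na(lw)) {
      expect_equal(loewe_effect(swapped, b, a), lw, tolerance = 1e-8)
    }
    expect_equal(hand_effect(swapped, b, a), hand_effect(pair, a, b),
                 tolerance = 1e-6)
    expect_equal(bliss_effect(swapped, b, a, normalise = TRUE),
                 bliss_effect(pair, a, b, normalise = TRUE),
                 tolerance = 1e-12)
    expect_equal(hsa_effect(swapped, b, a), hsa_effect(pair, a, b),
                 tolerance = 1e-12)
    ab <- tryCatch(tallarida_effect(pair, a, b, "a_to_b"),
                   combonull_equivalent_dose_undefined = function(c) NA)
    if (!is.na(ab)) {
      expect_equal(tallarida_effect(swapped, b, a, "b_to_a"), ab,
                   tolerance = 1e-12)
    }
  }
})

test_that("surfaces are non-decreasing in each dose", {
  set.seed(34)
  pair <- random_full_pair()
  doses_a <- sort(random_dose(pair$curve_a, 5))
  doses_b <- sort(random_dose(pair$curve_b, 5))
  for (model in c("loewe_hsa", "hand", "tallarida_lb", "tallarida_ub",
                  "bliss", "hsa")) {
    g <- evaluate_surface(null_surface(model, pair), doses_a, doses_b)
    expect_true(all(apply(g$effect, 2, function(col) all(diff(col) >= -1e-7))),
                label = paste(model, "rows"))
    expect_true(all(apply(g$effect, 1, function(row) all(diff(row) >= -1e-7))),
                label = paste(model, "cols"))
  }
})

test_that("evaluate_surface reports monotherapy edges and undefined cells", {
  pair <- curve_pair(hill_curve(0, 0.7, 1, 2), hill_curve(0, 1, 1, 2))
  b_lim <- hill_inverse(pair$curve_b, 0.7)
  grid <- evaluate_surface(null_surface("loewe", pair),
                           c(0, 0.5, 1), c(0, 0.5 * b_lim, 2 * b_lim))
  expect_equal(grid$effect[, 1], hill_eval(pair$curve_a, c(0, 0.5, 1)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(grid$effect[1, ], hill_eval(pair$curve_b,
                                           c(0, 0.5 * b_lim, 2 * b_lim)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(grid$status[2, 3], "undefined_loewe")
  expect_true(is.nan(grid$effect[2, 3]))
  expect_identical(grid$status[2, 2], "ok")
})

test_that("constant-potency pairs make loewe, hand and tallarida surfaces coincide", {
  set.seed(35)
  pair <- random_constant_potency_pair()
  da <- pair$curve_a$ec50 * 2^(-2:1)
  db <- pair$curve_b$ec50 * 2^(-2:1)
  mats <- lapply(c("loewe", "hand", "tallarida_ab", "tallarida_ba"),
                 function(m) evaluate_surface(null_surface(m, pair), da, db)$effect)
  for (m in mats[-1]) expect_equal(m, mats[[1]], tolerance = 1e-6)
})
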