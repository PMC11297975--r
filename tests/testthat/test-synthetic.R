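test_that("pen generator is a pure seeded function with exact means at sigma 0", {
  a <- sim_pen_responses("m2", beta = c(intercept = 1, oil = 0.1),
    sigma = 0, seed = 1
  )
  expect_equal(a$y[a$rapeseed_oil == 24], c(3.4, 3.4))
  expect_equal(nrow(a), 12)
  expect_false(anyDuplicated(a[c("size", "rapeseed_oil")]) > 0)

  b1 <- sim_pen_responses("m5",
    beta = c(intercept = 1, size = 2, oil = 0.3, interaction = -0.1),
    sigma = 0.7, seed = 99
  )
  b2 <- sim_pen_responses("m5",
    beta = c(intercept = 1, size = 2, oil = 0.3, interaction = -0.1),
    sigma = 0.7, seed = 99
  )
  expect_identical(b1, b2)

  # the global RNG stream is left untouched
  set.seed(123)
  before <- .Random.seed
  invisible(sim_pen_responses("m1", beta = c(intercept = 0), sigma = 1,
    seed = 7
  ))
  expect_identical(.Random.seed, before)

  # unused coefficients are ignored under the generating model
  c1 <- sim_pen_responses("m1", beta = c(intercept = 5, size = 100),
    sigma = 0, seed = 1
  )
  expect_equal(c1$y, rep(5, 12))
})

test_that("generated m3 data pipe end-to-end into correct recovery", {
  tab <- sim_pen_responses("m3", beta = c(intercept = 2, size = 3),
    sigma = 0.3, seed = 77
  )
  fit <- bms(tab, "y")
  expect_equal(fit$best_model, "m3")
  expect_gt(fit$probabilities["m3"], 0.99)
})

test_that("histology score generator matches the proportional-odds model", {
  tab <- sim_histology_scores(c(-0.8, 0, 0.8), fish_per_pen = 500,
    oil_levels = 0, sizes = c(0, 1), seed = 5
  )
  # beta = 0, symmetric cutpoints: outer categories match, inner symmetric
  freq <- tapply(tab$count, tab$score, sum) / sum(tab$count)
  probs <- diff(c(0, plogis(c(-0.8, 0, 0.8)), 1))
  expect_equal(as.numeric(freq), probs, tolerance = 0.05)

  # strong oil effect: mean score increases with oil level
  big <- sim_histology_scores(c(-1, 0, 1), beta_oil = 0.15,
    fish_per_pen = 1e4, sizes = 0, seed = 6
  )
  mean_by_oil <- vapply(
    sort(unique(big$rapeseed_oil)),
    function(o) {
      sub <- big[big$rapeseed_oil == o, ]
      sum(sub$score * sub$count) / sum(sub$count)
    },
    numeric(1)
  )
  expect_true(all(diff(mean_by_oil) > 0))

  # recovery of beta_size at n = 1e4 per cell
  rec <- sim_histology_scores(c(-1, 0.5, 2), beta_size = 0.9, beta_oil = 0,
    fish_per_pen = 1e4, oil_levels = 0, seed = 8
  )
  fit <- fit_proportional_odds(rec, terms = "size")
  expect_lt(abs(coef(fit)["size"] - 0.9), 0.1)
})

test_that("digestibility generator inverts the marker formula exactly", {
  tr <- sim_digestibility_trial(c(fat = 95, protein = 87, starch = 52))
  rec <- with(tr, apparent_digestibility(
    marker_feed, marker_faeces, nutrient_feed, nutrient_faeces
  ))
  expect_equal(rec, tr$true_ad)

  # zero digestibility: faeces/feed nutrient ratio equals the marker factor
  z <- sim_digestibility_trial(c(inert = 0), concentration_factor = 4)
  expect_equal(z$nutrient_faeces / z$nutrient_feed, 4)

  expect_error(sim_digestibility_trial(c(x = 101)), "config error")
})

test_that("noisy digestibility recovery is unbiased to 0.2 percent units", {
  recovered <- vapply(1:500, function(s) {
    tr <- sim_digestibility_trial(c(fat = 85), noise_sd = 0.01,
      seed = 70000 + s
    )
    with(tr, apparent_digestibility(
      marker_feed, marker_faeces, nutrient_feed, nutrient_faeces
    ))
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 85), 0.2)
})

test_that("dose-response generator validates its parametric families", {
  lin <- sim_dose_response("linear", c(intercept = 4.5, slope = -1 / 1000))
  expect_s3_class(lin, "dose_response_curve")
  # inverse consistency is exact on the linear family
  expect_equal(dose_at_score(lin, score_at_dose(lin, 1234)), 1234)

  lgs <- sim_dose_response("logistic",
    c(s_min = 0.5, s_max = 4.5, d50 = 1700, scale = 400)
  )
  expect_true(all(diff(lgs$score) <= 0))
  # matches the grid-inversion oracle within 1 mg/kg
  expect_lt(
    abs(dose_at_score(lgs, 2.5) - oracle_dose_at_score(lgs, 2.5)), 1
  )

  expect_error(
    sim_dose_response("linear", c(intercept = 4.5, slope = 0.001)),
    "config error"
  )
  expect_error(
    sim_dose_response("logistic",
      c(s_min = 4.5, s_max = 0.5, d50 = 1700, scale = 400)
    ),
    "config error"
  )
})
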