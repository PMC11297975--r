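two_group_table <- function(counts0, counts1, scores = seq_along(counts0) - 1) {
  data.frame(
    size = rep(c(0, 1), each = length(scores)),
    rapeseed_oil = 0,
    score = rep(scores, 2),
    count = c(counts0, counts1)
  )
}

test_that("identical score distributions give a null size effect", {
  tab <- two_group_table(c(5, 10, 15, 10, 5), c(5, 10, 15, 10, 5))
  fit <- fit_proportional_odds(tab, terms = "size")
  expect_lt(abs(coef(fit)["size"]), 1e-6)
  expect_equal(unname(exp(coef(fit)["size"])), 1, tolerance = 1e-5)
})

test_that("binary collapse equals the closed-form log odds ratio", {
  tab <- two_group_table(c(20, 10), c(10, 20))
  fit <- fit_proportional_odds(tab, terms = "size")
  expect_equal(unname(coef(fit)["size"]), log(4), tolerance = 1e-6)

  # a second 2x2 with a different odds ratio
  tab2 <- two_group_table(c(30, 10), c(12, 18))
  fit2 <- fit_proportional_odds(tab2, terms = "size")
  expect_equal(unname(coef(fit2)["size"]), log((30 / 10) / (12 / 18)),
    tolerance = 1e-6
  )
})

test_that("fit agrees with the reference polr implementation", {
  skip_if_not_installed("MASS")
  tab <- sim_histology_scores(c(-1.2, 0.2, 1.4, 2.8),
    beta_size = 0.8, beta_oil = 0.05, fish_per_pen = 40, seed = 11
  )
  fit <- fit_proportional_odds(tab)

  long <- tab[rep(seq_len(nrow(tab)), tab$count), ]
  long$score <- factor(long$score, ordered = TRUE)
  ref <- MASS::polr(score ~ size + rapeseed_oil, data = long, Hess = TRUE)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$zeta), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(unname(fit$logLik), unname(as.numeric(logLik(ref))),
    tolerance = 1e-8
  )
  # standard errors from the observed information
  ref_se <- sqrt(diag(vcov(ref)))[c("size", "rapeseed_oil")]
  expect_equal(unname(fit$se[c("size", "rapeseed_oil")]), unname(ref_se),
    tolerance = 1e-3
  )
})

test_that("likelihood never decreases across accepted Newton steps", {
  tab <- sim_histology_scores(c(-1, 0, 1, 2),
    beta_size = 1.5, beta_oil = 0.1, fish_per_pen = 25, seed = 3
  )
  fit <- fit_proportional_odds(tab)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) >= -1e-12))
  expect_true(!is.unsorted(fit$zeta, strictly = TRUE))
})

test_that("degenerate and separated tables raise informative errors", {
  one_cat <- data.frame(
    size = c(0, 1), rapeseed_oil = 0, score = 2, count = c(10, 12)
  )
  expect_error(fit_proportional_odds(one_cat), "degenerate")
  expect_error(score_table(one_cat), "degenerate")

  const_cov <- two_group_table(c(5, 5), c(5, 5))
  const_cov$size <- 0
  expect_error(fit_proportional_odds(const_cov, terms = "size"), "vary")

  # complete separation: all small fish score 0, all large score 1
  sep <- two_group_table(c(20, 0), c(0, 20))
  expect_error(fit_proportional_odds(sep, terms = "size"), "non-convergence")
})

test_that("empty interior categories are merged with a warning", {
  tab <- two_group_table(c(5, 0, 10, 8), c(9, 0, 7, 3))
  expect_warning(fit <- fit_proportional_odds(tab, terms = "size"), "merged")
  expect_equal(fit$categories, c(0, 2, 3))
})

test_that("Wald p-values follow the normal approximation", {
  tab <- two_group_table(c(20, 10), c(10, 20))
  fit <- fit_proportional_odds(tab, terms = "size")
  z <- coef(fit)["size"] / fit$se["size"]
  expect_equal(wald_p(fit, "size"), unname(2 * pnorm(-abs(z))))
  expect_error(wald_p(fit, "rapeseed_oil"), "unknown term")

  # null distributions: symmetric table gives p = 1
  null_fit <- fit_proportional_odds(
    two_group_table(c(8, 12, 8), c(8, 12, 8)),
    terms = "size"
  )
  expect_equal(wald_p(null_fit, "size"), 1, tolerance = 1e-4)
})

test_that("Wald test type-I error is near nominal over 500 null tables", {
  rej <- vapply(1:500, function(s) {
    tab <- sim_histology_scores(c(-1, 0.5, 2),
      beta_size = 0, beta_oil = 0, fish_per_pen = 60,
      oil_levels = 0, seed = 50000 + s
    )
    fit <- fit_proportional_odds(tab, terms = "size")
    wald_p(fit, "size") < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("parameter recovery: mean estimate within 0.1 of the truth", {
  ests <- vapply(1:200, function(s) {
    tab <- sim_histology_scores(c(-1, 0.5, 2),
      beta_size = 0.9, beta_oil = 0, fish_per_pen = 60,
      oil_levels = 0, seed = 60000 + s
    )
    coef(fit_proportional_odds(tab, terms = "size"))["size"]
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.9), 0.1)
})

test_that("predicted category probabilities are simplexes with stochastic ordering", {
  fit <- fit_proportional_odds(
    sim_histology_scores(c(-1, 0, 1, 2),
      beta_size = 0.7, beta_oil = 0.08, fish_per_pen = 50, seed = 21
    )
  )
  # zero-covariate case with a single 0 cutpoint is the fair coin
  flat <- fit_proportional_odds(
    two_group_table(c(10, 10), c(10, 10)),
    terms = "size"
  )
  p0 <- predicted_category_probs(flat, size = 0, rapeseed_oil = 0)
  expect_equal(drop(p0), c(`0` = 0.5, `1` = 0.5), tolerance = 1e-6)

  P <- predicted_category_probs(fit,
    size = c(0, 0, 1), rapeseed_oil = c(0, 24, 24)
  )
  expect_equal(rowSums(P), rep(1, 3))
  expect_true(all(P > 0 & P < 1))
  # increasing eta shifts mass upward: cumulative probs decrease row-wise
  cumP <- t(apply(P, 1, cumsum))
  expect_true(all(diff(cumP[, -ncol(cumP)]) <= 1e-12))

  # large-sample agreement with empirical frequencies
  big <- sim_histology_scores(c(-1, 0, 1, 2),
    beta_size = 0.7, beta_oil = 0.08, fish_per_pen = 1e4, seed = 99
  )
  bigfit <- fit_proportional_odds(big)
  emp <- with(
    subset(big, size == 1 & rapeseed_oil == 24),
    count / sum(count)
  )
  pred <- predicted_category_probs(bigfit, size = 1, rapeseed_oil = 24)
  expect_equal(drop(pred), setNames(emp, colnames(pred)), tolerance = 0.02)
})

test_that("score table CSV reader applies the documented schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c(
      "size,rapeseed_oil,score,count",
      "0,0,0,5", "0,0,1,7", "1,0,0,9", "1,0,1,3"
    ),
    path
  )
  tab <- read_score_table(path, endpoint = "steatosis_PI")
  expect_s3_class(tab, "score_table")
  expect_equal(attr(tab, "endpoint"), "steatosis_PI")
  expect_equal(sum(tab$count), 24)
})
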