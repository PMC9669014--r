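test_that("incidence reproduces the published field percentages", {
  expect_equal(incidence(268, 445)$percent, 60)
  expect_equal(incidence(451, 1883)$percent, 24)
  expect_equal(incidence(0, 10)$proportion, 0)
  expect_error(incidence(5, 0), "positive")
  expect_error(incidence(11, 10), "exceed")
})

test_that("quasibinomial incidence comparison behaves and scales correctly", {
  a <- data.frame(attacked = c(30, 40, 20), examined = c(100, 120, 80))
  b <- data.frame(attacked = c(15, 25, 22), examined = c(50, 75, 88))
  # identical per-site proportions in both groups: F ~ 0
  same <- compareIncidence(a, a)
  expect_lt(same$F, 1e-10)
  # F equals the dispersion-scaled deviance difference computed by hand
  res <- compareIncidence(a, b)
  dat <- rbind(data.frame(a, species = "A"), data.frame(b, species = "B"))
  fit1 <- glm(cbind(attacked, examined - attacked) ~ species,
              family = binomial, data = dat)
  fit0 <- glm(cbind(attacked, examined - attacked) ~ 1,
              family = binomial, data = dat)
  disp <- sum(residuals(fit1, "pearson")^2) / fit1$df.residual
  Fman <- (deviance(fit0) - deviance(fit1)) / 1 / disp
  expect_equal(res$F, Fman, tolerance = 1e-4)
  expect_equal(res$df, 1L)
  # doubling all counts leaves the fitted proportions unchanged
  res2 <- compareIncidence(a * 2, b * 2)
  expect_equal(unname(fitted(res2$fit)), unname(fitted(res$fit)),
               tolerance = 1e-10)
  # complete separation is flagged
  sep <- compareIncidence(data.frame(attacked = c(0, 0),
                                     examined = c(30, 40)), b)
  expect_true(sep$separation)
})

test_that("availability chi-square follows the hand computation", {
  prop <- availabilityChiSquare(c(20, 20), c(0.5, 0.5))
  expect_equal(prop$chi2, 0)
  res <- availabilityChiSquare(c(30, 10), c(0.5, 0.5))
  expect_equal(res$chi2, 10)
  expect_equal(res$df, 1L)
  expect_equal(res$p, pchisq(10, 1, lower.tail = FALSE))
  # invariant to category order
  res2 <- availabilityChiSquare(c(10, 30), c(0.5, 0.5))
  expect_equal(res2$chi2, res$chi2)
  expect_error(availabilityChiSquare(c(5, 5), c(0.7, 0.2)), "sum to 1")
  expect_error(availabilityChiSquare(c(5, 5), c(1, 0)), "zero expected")
})

test_that("Bonferroni t intervals match the quantile table and widen with k", {
  expect_equal(unname(bonferroniCI(0, 50, 3)), c(0, 0))
  ci <- bonferroniCI(0.5, 100, 1)
  half <- qt(0.975, 99) * sqrt(0.25 / 100)
  expect_equal(unname(ci), c(0.5 - half, 0.5 + half), tolerance = 1e-10)
  expect_equal(half, 0.0992, tolerance = 1e-3)
  w <- vapply(1:6, function(k) diff(bonferroniCI(0.3, 80, k)), numeric(1))
  expect_true(all(diff(w) > 0))
  # negative lower bounds are reported un-truncated unless clamped
  lowUse <- bonferroniCI(0.01, 40, 8)
  expect_lt(lowUse[1], 0)
  expect_gte(bonferroniCI(0.01, 40, 8, clamp = TRUE)[1], 0)
})

test_that("use classification reproduces the published calls and partitions", {
  expect_equal(classifyUse(0.470, c(0.657, 0.806)), "preference")
  expect_equal(classifyUse(0.299, c(0.221, 0.376)), "proportional")
  expect_equal(classifyUse(0.236, c(0.017, 0.095)), "avoidance")
  expect_equal(classifyUse(0.225, c(0.005, 0.069)), "avoidance")
  # total function over the real line given any interval
  ci <- c(0.2, 0.4)
  cls <- vapply(c(-1, 0.19, 0.2, 0.3, 0.4, 0.41, 2), classifyUse,
                character(1), ci = ci)
  expect_equal(cls, c("preference", "preference", "proportional",
                      "proportional", "proportional", "avoidance",
                      "avoidance"))
  expect_error(classifyUse(0.3, c(0.5, 0.4)), "interval")
})

test_that("the Neu analysis recovers a planted strong preference", {
  avail <- data.frame(site = "s1", taxon = c("A", "B", "C", "D"),
                      available = c(500, 400, 300, 200))
  sim <- simHostSurvey(avail, weights = c(A = 5, B = 1, C = 1, D = 0.2),
                       nAttacks = 300, seed = 42)
  res <- neuAnalysis(sim$survey, by = "taxon")
  expect_true(res$selectionDetected)
  tab <- res$table
  expect_equal(tab$classification[tab$category == "A"], "preference")
  expect_equal(tab$classification[tab$category == "D"], "avoidance")
  expect_equal(sum(tab$ppa), 1)
  expect_true(all(tab$ciLow <= tab$ciHigh))
  # survey I/O round trip
  f <- tempfile()
  write.table(sim$survey, f, row.names = FALSE, quote = FALSE)
  expect_equal(readHostSurvey(f), sim$survey, ignore_attr = TRUE)
})
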