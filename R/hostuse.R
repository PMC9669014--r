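#' Attack incidence
#'
#' @param attacked number of plants found infested.
#' @param examined number of plants inspected (> 0).
#' @return List with `proportion` and `percent` (rounded to whole percent).
#' @examples
#' incidence(268, 445)  # 60%
#' @export
incidence <- function(attacked, examined) {
  if (examined <= 0) stop("examined must be positive")
  if (attacked > examined) stop("attacked cannot exceed examined")
  p <- attacked / examined
  list(proportion = p, percent = round(100 * p))
}

#' Compare attack incidence between two species with a quasibinomial GLM
#'
#' Site-level attacked/examined counts for each species are modelled with a
#' binomial GLM (logit link) with species as the only factor; overdispersion
#' is absorbed by the quasibinomial dispersion estimate (Pearson statistic)
#' and the species term is assessed with an F test on the scaled deviance
#' difference.
#'
#' @param surveyA,surveyB data.frames with columns `attacked` and `examined`
#'   (one row per site).
#' @return List with `F`, `df`, `residDf`, `p`, `dispersion` and the fitted
#'   `glm` object. Complete separation (all-0 or all-1 within a group) is
#'   flagged via `separation`.
#' @export
compareIncidence <- function(surveyA, surveyB) {
  dat <- rbind(data.frame(surveyA[c("attacked", "examined")], species = "A"),
               data.frame(surveyB[c("attacked", "examined")], species = "B"))
  if (nrow(dat) < 2L) stop("need at least 2 sites in total")
  dat$species <- factor(dat$species)
  prop <- with(dat, tapply(attacked, species, sum) /
                 tapply(examined, species, sum))
  separation <- any(prop %in% c(0, 1))
  fit <- stats::glm(cbind(attacked, examined - attacked) ~ species,
                    family = stats::quasibinomial(link = "logit"), data = dat)
  an <- stats::anova(fit, test = "F")
  list(F = an$F[2], df = an$Df[2], residDf = an$`Resid. Df`[2],
       p = an$`Pr(>F)`[2], dispersion = summary(fit)$dispersion,
       separation = separation, fit = fit)
}

#' Chi-square goodness of fit of use against availability
#'
#' Omnibus test of the Neu method's first null hypothesis: attacks are
#' distributed across categories in proportion to availability.
#'
#' @param used attacked counts per category.
#' @param availability availability proportions per category (sum to 1).
#' @return List with `chi2`, `df`, `p`, `expected`.
#' @export
availabilityChiSquare <- function(used, availability) {
  if (abs(sum(availability) - 1) > 1e-8)
    stop("availability proportions must sum to 1")
  U <- sum(used)
  if (U <= 0) stop("no attacks observed")
  expd <- U * availability
  if (any(expd == 0))
    stop("zero expected count; merge categories with zero availability")
  chi2 <- sum((used - expd)^2 / expd)
  df <- length(used) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = expd)
}

#' Bonferroni simultaneous confidence interval for a use proportion
#'
#' `p_hat +/- t(alpha / 2k, n - 1) * sqrt(p_hat (1 - p_hat) / n)`, the
#' Bonferroni-adjusted Student-t interval of the Neu method for `k`
#' simultaneous categories and `n` total used (attacked) plants. Bounds are
#' not truncated to `[0, 1]` by default, matching how such intervals are
#' conventionally reported (a small-use category can have a negative lower
#' bound).
#'
#' @param pHat share of attacks falling on the category.
#' @param n total attacked plants at the analysis level (>= 2).
#' @param k number of simultaneous categories.
#' @param alpha familywise two-sided level (default 0.05).
#' @param clamp truncate the interval to `[0, 1]`.
#' @return Numeric `c(low, high)`.
#' @export
bonferroniCI <- function(pHat, n, k, alpha = 0.05, clamp = FALSE) {
  stopifnot(n >= 2, k >= 1)
  tq <- stats::qt(1 - alpha / (2 * k), df = n - 1)
  half <- tq * sqrt(pHat * (1 - pHat) / n)
  ci <- c(pHat - half, pHat + half)
  if (clamp) ci <- pmin(pmax(ci, 0), 1)
  stats::setNames(ci, c("low", "high"))
}

#' Classify host use against availability
#'
#' The Neu method's three scenarios: `preference` when use exceeds
#' availability (availability falls below the interval on the use
#' proportion), `proportional` when availability lies inside the interval,
#' and `avoidance` when use falls short of availability.
#'
#' @param ppa availability proportion of the category.
#' @param ci `c(low, high)` interval on the use proportion, e.g. from
#'   [bonferroniCI()].
#' @return One of `"preference"`, `"proportional"`, `"avoidance"`.
#' @examples
#' classifyUse(0.470, c(0.657, 0.806))  # preference
#' @export
classifyUse <- function(ppa, ci) {
  if (ci[1] > ci[2]) stop("invalid interval")
  if (ppa < ci[1]) "preference"
  else if (ppa <= ci[2]) "proportional"
  else "avoidance"
}

#' Neu-method resource-selection analysis of a host survey
#'
#' Aggregates a survey at taxon or site level, runs the omnibus chi-square
#' of use against availability, and, for the per-category step, computes the
#' attack-share proportion with its Bonferroni simultaneous interval and the
#' use classification. The per-category classification is meaningful when the
#' omnibus test rejects (`selectionDetected`); categories are classified
#' unconditionally in the output for transparency.
#'
#' @param survey data.frame with columns `site`, `taxon`, `available`,
#'   `attacked` (see [readHostSurvey()]).
#' @param by analysis level, `"taxon"` or `"site"`.
#' @param alpha familywise level for the simultaneous intervals and the
#'   omnibus test.
#' @param clamp truncate intervals to `[0, 1]`.
#' @return List with `table` (category, available, attacked, ppa, pUsed,
#'   ciLow, ciHigh, classification), `chi2`, `df`, `p`,
#'   `selectionDetected`, `nUsed`.
#' @export
neuAnalysis <- function(survey, by = c("taxon", "site"), alpha = 0.05,
                        clamp = FALSE) {
  by <- match.arg(by)
  agg <- stats::aggregate(survey[c("available", "attacked")],
                          by = list(category = survey[[by]]), FUN = sum)
  ppa <- agg$available / sum(agg$available)
  nUsed <- sum(agg$attacked)
  pUsed <- agg$attacked / nUsed
  k <- nrow(agg)
  om <- availabilityChiSquare(agg$attacked, ppa)
  ci <- t(vapply(pUsed, bonferroniCI, numeric(2), n = nUsed, k = k,
                 alpha = alpha, clamp = clamp))
  cls <- vapply(seq_len(k), function(j) classifyUse(ppa[j], ci[j, ]),
                character(1))
  tab <- data.frame(category = agg$category, available = agg$available,
                    attacked = agg$attacked, ppa = ppa, pUsed = pUsed,
                    ciLow = ci[, 1], ciHigh = ci[, 2], classification = cls)
  list(table = tab, chi2 = om$chi2, df = om$df, p = om$p,
       selectionDetected = om$p < alpha, nUsed = nUsed)
}
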