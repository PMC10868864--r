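# Balanced pair data whose sample moments exactly equal the model-implied
# moments: both members mean 0, variance 1, and an exact sample correlation.
exact_moment_pairs <- function(n, r, seed) {
  set.seed(seed)
  gs <- function(n, r) {
    a <- rnorm(n); a <- (a - mean(a)) / sd(a)
    u <- rnorm(n); u <- u - mean(u)
    u <- u - a * sum(a * u) / sum(a * a)
    u <- u / sd(u)
    cbind(a, r * a + sqrt(1 - r^2) * u)
  }
  mz <- gs(n, r[1]); dz <- gs(n, r[2])
  make <- function(m, zyg, off) {
    data.frame(family_id = sprintf("f%05d", off + seq_len(nrow(m))),
               zygosity = zyg, sex = "M", race_eth = "White",
               age_months = 120, y_1 = m[, 1], y_2 = m[, 2],
               stringsAsFactors = FALSE)
  }
  out <- rbind(make(mz, "MZ", 0), make(dz, "DZ", n))
  class(out) <- c("twin_pairs", "data.frame")
  out
}

test_that("falconer reproduces the moment arithmetic with truncation", {
  f <- falconer(0.19, 0.05)
  expect_equal(f$h2, 0.28)
  expect_equal(f$c2, 0)            # truncated from -0.09
  expect_equal(f$raw[["c2"]], -0.09)
  expect_equal(f$e2, 0.72)

  f2 <- falconer(0.44, 0.44)
  expect_equal(f2$h2, 0)
  expect_equal(f2$c2, 0.44)
  expect_equal(f2$e2, 0.56)

  expect_equal(falconer(0.50, 0.30)$h2, 0.40)
  expect_equal(f$h2 + f$c2 + f$e2, 1)
})

test_that("orthant probabilities hit closed forms and quadrants sum to one", {
  expect_equal(orthant_probability(0, 0, 0), 0.25)
  expect_equal(orthant_probability(0, 0, 1), 0.5)
  expect_equal(orthant_probability(1.2, -0.4, 1),
               pnorm(1.2, lower.tail = FALSE))
  expect_equal(orthant_probability(0.3, 0.4, -1),
               max(0, 1 - pnorm(0.3) - pnorm(0.4)))
  expect_error(orthant_probability(0, 0, 1.5), "rho")

  set.seed(14)
  for (i in 1:20) {
    t1 <- rnorm(1); t2 <- rnorm(1); rho <- runif(1, -0.95, 0.95)
    p11 <- orthant_probability(t1, t2, rho)
    p10 <- pnorm(t1, lower.tail = FALSE) - p11
    p01 <- pnorm(t2, lower.tail = FALSE) - p11
    p00 <- 1 - pnorm(t1, lower.tail = FALSE) - pnorm(t2, lower.tail = FALSE) + p11
    expect_lt(abs(p11 + p10 + p01 + p00 - 1), 1e-9)
    expect_true(all(c(p11, p10, p01, p00) >= -1e-12))
    # symmetry in the thresholds
    expect_equal(p11, orthant_probability(t2, t1, rho), tolerance = 1e-12)
  }
})

test_that("continuous ML recovers simulated variance components", {
  est <- sapply(61:64, function(s) {
    fit <- fit_ace(sim_continuous(5000, a2 = 0.5, c2 = 0.2, seed = s),
                   "y", "ACE")
    expect_equal(sum(fit$estimates), 1, tolerance = 1e-8)
    expect_true(all(fit$estimates >= 0))
    fit$estimates
  })
  expect_lt(abs(mean(est["h2", ]) - 0.5), 0.04)
  expect_lt(abs(mean(est["c2", ]) - 0.2), 0.04)

  # uncorrelated pairs: everything loads on unique environment
  pairs0 <- sim_continuous(3000, a2 = 0, c2 = 0, seed = 62)
  fit0 <- fit_ace(pairs0, "y", "ACE")
  expect_gt(fit0$estimates[["e2"]], 0.93)
})

test_that("ML coincides with the moment decomposition on exact-moment data", {
  pairs <- exact_moment_pairs(500, c(0.5, 0.3), seed = 63)
  fit <- fit_ace(pairs, "y", "ACE")
  mom <- falconer(0.5, 0.3)
  expect_lt(abs(fit$estimates[["h2"]] - mom$h2), 1e-4)
  expect_lt(abs(fit$estimates[["c2"]] - mom$c2), 1e-4)
  expect_lt(abs(fit$estimates[["e2"]] - mom$e2), 1e-4)
})

test_that("binary liability ML recovers simulated components", {
  pairs <- sim_binary(10000, a2 = 0.5, c2 = 0.2, prevalence = 0.25, seed = 64)
  fit <- fit_ace(pairs, "y", "ACE")
  expect_equal(fit$scale, "liability")
  expect_lt(abs(fit$estimates[["h2"]] - 0.5), 0.07)
  expect_lt(abs(fit$estimates[["c2"]] - 0.2), 0.07)
  expect_lt(abs(fit$threshold - qnorm(0.75)), 0.05)

  pairs0 <- sim_binary(10000, a2 = 0, c2 = 0, prevalence = 0.25, seed = 65)
  fit0 <- fit_ace(pairs0, "y", "ACE")
  expect_lt(fit0$estimates[["h2"]], 0.08)
  expect_lt(fit0$estimates[["c2"]], 0.08)
})

test_that("Wald intervals follow the untruncated +/- 1.96 SE contract", {
  fake <- list(estimates = c(h2 = 0.04), se = c(h2 = 0.17))
  ci <- wald_ci(fake)
  expect_equal(ci$lower, 0.04 - 1.96 * 0.17)
  expect_equal(ci$upper, 0.04 + 1.96 * 0.17)
  expect_lt(ci$lower, 0)   # negative bounds are reported as-is
  expect_equal(ci$p, 2 * pnorm(-0.04 / 0.17), tolerance = 1e-12)

  # components fixed at zero by the model are absent from the table
  pairs <- sim_continuous(1000, a2 = 0.4, c2 = 0.1, seed = 66)
  ae <- fit_ace(pairs, "y", "AE")
  expect_false("c2" %in% wald_ci(ae)$component)
  expect_true(all(c("h2", "e2") %in% wald_ci(ae)$component))
})

test_that("component CI width shrinks like 1/sqrt(n)", {
  small <- fit_ace(sim_continuous(1250, 0.4, 0.2, seed = 67), "y", "ACE")
  big <- fit_ace(sim_continuous(5000, 0.4, 0.2, seed = 68), "y", "ACE")
  se_ratio <- small$components$se[1] / big$components$se[1]
  expect_lt(abs(se_ratio - 2), 0.3)
})

test_that("model comparison reduces at boundaries and otherwise minimizes BIC", {
  # intent-like truth: c2 = 0 drives AE reduction
  pairs <- sim_continuous(3000, a2 = 0.3, c2 = 0, seed = 69)
  fits <- fit_ace_ladder(pairs, "y")
  # nesting dominance on this dataset
  expect_gte(fits$ACE$loglik + 1e-6, fits$AE$loglik)
  expect_gte(fits$AE$loglik + 1e-6, fits$E$loglik)
  expect_gte(fits$ACE$loglik + 1e-6, fits$CE$loglik)
  if (fits$ACE$estimates[["c2"]] < 1e-6) {
    sel <- compare_and_reduce(fits)
    expect_equal(sel$model, "AE")
    expect_match(attr(sel, "selection"), "boundary")
  }
  # forced-boundary fit list exercises the rule deterministically
  fits2 <- fits
  fits2$ACE$estimates["c2"] <- 0
  expect_equal(compare_and_reduce(fits2)$model, "AE")
  fits3 <- fits
  fits3$ACE$estimates[c("h2", "c2")] <- c(0, 0.3)
  expect_equal(compare_and_reduce(fits3)$model, "CE")
  # interior optimum: BIC decides
  fits4 <- fits
  fits4$ACE$estimates[c("h2", "c2")] <- c(0.2, 0.2)
  sel4 <- compare_and_reduce(fits4)
  bics <- vapply(fits4, `[[`, 0, "bic")
  expect_equal(sel4$bic, min(bics))
})

test_that("selection is consistent when the truth is a CE model", {
  picks <- character(100)
  for (i in 1:100) {
    pairs <- sim_continuous(2000, a2 = 0, c2 = 0.5, seed = 700 + i)
    sel <- compare_and_reduce(fit_ace_ladder(pairs, "y"))
    picks[i] <- if (sel$model == "CE" ||
                    (sel$model == "ACE" && sel$estimates[["h2"]] < 0.01)) {
      "ce_like"
    } else {
      sel$model
    }
  }
  expect_gte(mean(picks == "ce_like"), 0.90)
})

test_that("stratified analysis matches the unstratified fit and survives tiny strata", {
  pairs <- sim_continuous(2000, a2 = 0.4, c2 = 0.2, seed = 71)
  tab <- stratified_ace(pairs, "y", "sex")   # single stratum (all M)
  expect_equal(nrow(tab), 1)
  ref <- compare_and_reduce(fit_ace_ladder(pairs, "y"))
  expect_equal(tab$model, ref$model)
  expect_equal(tab$h2, unname(ref$estimates["h2"]), tolerance = 1e-10)
  expect_equal(tab$bic, ref$bic, tolerance = 1e-10)

  tiny <- pairs
  tiny$sex[1:5] <- "F"
  tiny$sex[-(1:5)] <- "M"
  tab2 <- stratified_ace(tiny, "y", "sex")
  frow <- tab2[tab2$stratum == "F", ]
  expect_match(frow$status, "descriptives only")
  expect_true(is.na(frow$h2))
  expect_false(is.na(frow$r_mz) && is.na(frow$r_dz))
})

test_that("stratum-specific shared environment is recovered for a binary trait", {
  strata <- data.frame(sex = c("M", "F"), race_eth = "White",
                       weight = c(0.5, 0.5), stringsAsFactors = FALSE)
  comps <- rbind(c(0.09, 0.55, 0.36), c(0.03, 0.63, 0.34))
  cfg <- twin_sim_config(
    n_pairs = 40000, dz_fraction = 0.5, strata = strata,
    traits = list(sim_trait("y", "binary", prevalence = 0.25,
                            components = comps)),
    seed = 72)
  pairs <- pair_twins(simulate_cohort(cfg))
  tab <- stratified_ace(pairs, "y", "sex", model = "ACE")
  c2_m <- tab$c2[tab$stratum == "M"]
  c2_f <- tab$c2[tab$stratum == "F"]
  expect_lt(abs(c2_m - 0.55), 0.05)
  expect_lt(abs(c2_f - 0.63), 0.05)
  expect_true(all(tab$model == "ACE"))
})

test_that("covariates shift the mean without disturbing the components", {
  pairs <- sim_continuous(3000, a2 = 0.4, c2 = 0.2, seed = 73)
  pairs$y_1 <- pairs$y_1 + 0.02 * pairs$age_months
  pairs$y_2 <- pairs$y_2 + 0.02 * pairs$age_months
  fit <- fit_ace(pairs, "y", "ACE", covariates = "age_months")
  expect_lt(abs(fit$beta[["age_months"]] - 0.02), 0.005)
  expect_lt(abs(fit$estimates[["h2"]] - 0.4), 0.06)
})
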