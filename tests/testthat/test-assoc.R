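test_that("logistic fit matches the 2x2 closed form and detects optimality", {
  y <- c(rep(1, 100), rep(0, 100))
  x <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  f <- fit_logistic(y, cbind(x))
  expect_equal(unname(f$coef[2]), log(30 * 90 / (70 * 10)), tolerance = 1e-6)
  expect_equal(unname(f$se[2]), sqrt(1 / 30 + 1 / 70 + 1 / 10 + 1 / 90),
               tolerance = 1e-6)
  expect_true(f$converged)
  # symmetric design: beta is zero to numerical precision
  y2 <- rep(c(1, 0), 50)
  x2 <- rep(c(1, 1, 0, 0), 25)
  f2 <- fit_logistic(y2, cbind(x2))
  expect_lt(abs(f2$coef[2]), 1e-8)
  # ML optimality: no random parameter point beats the optimum
  ll_at <- function(b) {
    eta <- cbind(1, x) %*% b
    sum(y * eta - log1p(exp(eta)))
  }
  set.seed(12)
  probes <- replicate(100, ll_at(f$coef + rnorm(2, 0, 0.5)))
  expect_true(all(probes <= f$loglik + 1e-10))
})

test_that("perfect separation is flagged, not silently returned", {
  y <- c(rep(1, 20), rep(0, 20))
  x <- c(rep(1, 20), rep(0, 20))
  f <- fit_logistic(y, cbind(x))
  expect_true(f$separation)
  expect_true(is.infinite(f$coef[2]))
  expect_error(fit_logistic(rep(1, 10), cbind(rnorm(10))), "single class")
})

test_that("model selection follows the lack-of-fit rule and homozygote gates", {
  # strong additive effect: additive model selected in most replicates
  set.seed(13)
  picks <- replicate(12, {
    g <- rbinom(3000, 2, 0.3)
    y <- rbinom(3000, 1, plogis(-1 + log(1.5) * g))
    test_snp(g, y)$model_used
  })
  expect_gte(mean(picks == "additive"), 0.75)
  # pure recessive penetrance: recessive picked more often than additive
  set.seed(14)
  picks_rec <- replicate(12, {
    g <- rbinom(4000, 2, 0.35)
    y <- rbinom(4000, 1, plogis(-1.2 + 1.2 * (g == 2)))
    test_snp(g, y)$model_used
  })
  expect_gt(sum(picks_rec == "recessive"), sum(picks_rec == "additive"))
  # 9 minor homozygotes: additive/recessive gated out, dominant reported
  g <- c(rep(2, 9), rep(1, 200), rep(0, 791))
  y <- rbinom(1000, 1, 0.4)
  r <- test_snp(g, y)
  expect_equal(r$model_used, "dominant")
  expect_match(r$note, "9 minor homozygotes")
  expect_true(is.na(r$p_additive))
})

test_that("results are reported on the coded-allele scale after flipping", {
  set.seed(15)
  g_minor <- rbinom(4000, 2, 0.25)
  y <- rbinom(4000, 1, plogis(-1 + 0.4 * g_minor))
  g_coded_major <- 2 - g_minor   # code the protective/major allele
  r_min <- test_snp(g_minor, y)
  r_maj <- test_snp(g_coded_major, y)
  expect_equal(r_maj$beta, -r_min$beta, tolerance = 1e-8)
})

test_that("tier assignment applies the three thresholds and BH step-up", {
  t1 <- assign_tiers(3e-9)
  expect_equal(t1$tier, "1")
  expect_equal(assign_tiers(0.5)$fdr_adjusted_p, 0.5)  # single p unchanged
  bh <- assign_tiers(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh$fdr_adjusted_p, rep(0.04, 4))
  mix <- assign_tiers(c(1e-9, 5e-7, 1e-3, 0.9))
  expect_equal(mix$tier, c("1", "2", "3", "none"))
  expect_true(all(mix$fdr_adjusted_p >= mix$p))
  expect_true(all(diff(sort(mix$fdr_adjusted_p)[rank(mix$p)]) >= 0))
})

test_that("regional stepwise recovers planted signals and stays empty on null", {
  set.seed(16)
  n <- 3000
  G <- sapply(1:10, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("s", 1:10)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * G[, 4]))
  sel <- regional_stepwise(G, y)
  expect_equal(sel$selected, "s4")
  expect_true(all(sel$conditional$p < 0.001))
  # two independent causal SNPs both found
  y2 <- rbinom(n, 1, plogis(-0.8 + log(1.8) * G[, 2] + log(1.8) * G[, 7]))
  sel2 <- regional_stepwise(G, y2)
  expect_setequal(sel2$selected, c("s2", "s7"))
  # null region stays empty
  y0 <- rbinom(n, 1, 0.4)
  expect_length(regional_stepwise(G, y0)$selected, 0)
  # collinear duplicate is skipped, not entered twice
  G2 <- cbind(G, s4dup = G[, 4])
  sel3 <- regional_stepwise(G2, y)
  expect_length(intersect(sel3$selected, c("s4", "s4dup")), 1)
})

test_that("stepwise ties break by genomic position and order does not matter", {
  set.seed(17)
  n <- 2500
  G <- sapply(1:6, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("s", 1:6)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * G[, 3]))
  a <- regional_stepwise(G, y, positions = 1:6)
  b <- regional_stepwise(G[, 6:1], y, positions = 6:1)
  expect_setequal(a$selected, b$selected)
})

test_that("SNP-SNP interaction LRT finds a planted product effect", {
  set.seed(18)
  n <- 6000
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  cp <- (g1 - mean(g1)) * (g2 - mean(g2))
  y <- rbinom(n, 1, plogis(-0.5 + 0.1 * g1 + 0.1 * g2 + 0.5 * cp))
  res <- interaction_scan("snp_snp", cbind(a = g1, b = g2), y)
  expect_lt(res$p, 1e-3)
  # no interaction: P is not extreme
  y0 <- rbinom(n, 1, plogis(-0.5 + 0.2 * g1 + 0.2 * g2))
  res0 <- interaction_scan("snp_snp", cbind(a = g1, b = g2), y0)
  expect_gt(res0$p, 1e-3)
})

test_that("case-only sex scan is null when sex is independent of genotype", {
  set.seed(19)
  n <- 3000
  G <- sapply(1:20, function(i) rbinom(n, 2, 0.3))
  y <- rbinom(n, 1, 0.5)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.9, 0.1))
  res <- interaction_scan("sex_caseonly", G, y, sex = sex)
  expect_equal(nrow(res), 20)
  expect_gt(min(res$p, na.rm = TRUE), 1e-4)  # no spurious strong hits
  expect_gt(mean(res$p > 0.1), 0.5)
})

test_that("chromosome X analysis stratifies by sex and recombines", {
  set.seed(20)
  n <- 4000
  wins <- replicate(10, {
    sex <- sample(c("F", "M"), n, replace = TRUE)
    g <- ifelse(sex == "F", rbinom(n, 2, 0.3), 2 * rbinom(n, 1, 0.3))
    y <- rbinom(n, 1, plogis(-0.8 + 0.25 * g))
    r <- chrx_association(g, y, sex)
    stopifnot(r$male_coding == "0/2", nrow(r$strata) == 2)
    r$combined$p_combined <= min(r$strata$p)
  })
  # with equal true effects the combination usually beats either stratum
  expect_gte(mean(wins), 0.6)
  # single-sex data: combination falls back to the stratum result
  sex <- rep("F", 2000)
  g <- rbinom(2000, 2, 0.3)
  y <- rbinom(2000, 1, plogis(-0.5 + 0.3 * g))
  r1 <- chrx_association(g, y, sex)
  expect_equal(r1$combined$p_combined, r1$strata$p[1])
})

test_that("expected discoveries match null arithmetic, Monte Carlo, and grow with n", {
  e0 <- expected_discoveries(rep(1, 40), rep(0.3, 40), 1000, 1000, 0.05)
  expect_equal(e0$expected, 40 * 0.05, tolerance = 1e-6)
  # Monte-Carlo oracle at the study's AA sample sizes
  set.seed(21)
  n_case <- 2970; n_ctrl <- 2452; or <- 1.5; raf <- 0.3; alpha <- 1e-6
  p_case <- or * raf / (1 - raf) / (1 + or * raf / (1 - raf))
  B <- 200000
  a <- rbinom(B, 2 * n_case, p_case); c <- rbinom(B, 2 * n_ctrl, raf)
  bet <- log(a / (2 * n_case - a)) - log(c / (2 * n_ctrl - c))
  se <- sqrt(1 / a + 1 / (2 * n_case - a) + 1 / c + 1 / (2 * n_ctrl - c))
  mc_power <- mean(abs(bet / se) > qnorm(1 - alpha / 2))
  ours <- expected_discoveries(or, raf, n_case, n_ctrl, alpha)$expected
  expect_equal(ours, mc_power, tolerance = 0.02)
  # monotone in sample size
  pw <- sapply(c(500, 2000, 8000), function(n)
    expected_discoveries(1.3, 0.25, n, n, 5e-8)$expected)
  expect_true(all(diff(pw) > 0))
})
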