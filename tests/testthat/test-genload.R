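test_that("train/test split is exact, disjoint, exhaustive and reproducible", {
  ids <- sprintf("S%05d", 1:18264)
  y <- c(rep(1, 6748), rep(0, 11516))
  sp <- split_train_test(ids, y, 2000, 2000, seed = 50)
  expect_length(sp$test, 4000)
  expect_length(sp$train, 18264 - 4000)
  expect_equal(sum(y[match(sp$train, ids)] == 1), 4748)
  expect_equal(sum(y[match(sp$train, ids)] == 0), 9516)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- split_train_test(ids, y, 2000, 2000, seed = 50)
  expect_identical(sp$test, sp2$test)
  expect_error(split_train_test(ids[1:100], y[1:100], 2000, 2000),
               "too small")
})

test_that("training weights are positive and recover planted SNPs", {
  set.seed(51)
  n <- 4000; m <- 30
  G <- sapply(1:m, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("s", 1:m)
  beta <- c(rep(log(1.4), 8), rep(0, m - 8))
  y <- rbinom(n, 1, plogis(-1 + G %*% beta))
  w <- select_training_weights(G, y, regions = rep(1:6, each = 5))
  expect_true(all(w$gamma > 0))
  expect_gte(sum(w$snp_id %in% paste0("s", 1:8)), 5)
  # null panel: empty weight set
  y0 <- rbinom(n, 1, 0.4)
  w0 <- select_training_weights(G, y0)
  expect_lte(nrow(w0), 1)
})

test_that("the load formula matches closed forms and is linear", {
  G <- rbind(a = c(2, 1), b = c(0, 0), c = c(1, 2))
  colnames(G) <- c("x", "y")
  w <- data.frame(snp_id = c("x", "y"), risk_allele_is_coded = TRUE,
                  gamma = c(log(1.5), log(2)))
  grs <- compute_grs(G, w, "weighted")
  expect_equal(grs$load[1], 2 * 0.405465 + 0.693147, tolerance = 1e-5)
  expect_equal(grs$load[2], 0)
  # unweighted mode is the plain risk-allele count
  grs_u <- compute_grs(G, w, "unweighted")
  expect_equal(grs_u$load, rowSums(G), ignore_attr = TRUE)
  # weighted equals unweighted when all gamma are 1
  w1 <- transform(w, gamma = 1)
  expect_equal(compute_grs(G, w1, "weighted")$load, grs_u$load)
  # additivity over SNP subsets without missing data
  l1 <- compute_grs(G[, 1, drop = FALSE], w[1, ], "weighted")$load
  l2 <- compute_grs(G[, 2, drop = FALSE], w[2, ], "weighted")$load
  expect_equal(l1 + l2, grs$load)
  # risk-allele flip: coded non-risk allele counts 2 - g
  wf <- transform(w, risk_allele_is_coded = c(FALSE, TRUE))
  grs_f <- compute_grs(G, wf, "unweighted")
  expect_equal(grs_f$load, (2 - G[, 1]) + G[, 2], ignore_attr = TRUE)
  # absent SNP dropped with warning
  w3 <- rbind(w, data.frame(snp_id = "zz", risk_allele_is_coded = TRUE,
                            gamma = 1))
  expect_warning(g3 <- compute_grs(G, w3, "weighted"), "absent")
  expect_equal(g3$n_snps[1], 2)
  # missing genotype contributes its frequency expectation
  G2 <- G; G2["a", "x"] <- NA
  grs_m <- compute_grs(G2, w, "unweighted")
  raf_x <- mean(G2[c("b", "c"), "x"]) / 2
  expect_equal(grs_m$load[1], 2 * raf_x + 1)
})

test_that("sliding windows are null-calibrated and ordered", {
  set.seed(52)
  n <- 4000
  load <- rbinom(n, 60, 0.4)   # load independent of status
  y <- rbinom(n, 1, 0.5)
  sw <- sliding_window_or(load, y, window_width = 20)
  ok <- !sw$windows$skipped
  expect_true(any(ok))
  covers <- sw$windows$ci_lo[ok] <= 1 & 1 <= sw$windows$ci_hi[ok]
  expect_gte(mean(covers), 0.85)
  expect_true(all(diff(sw$windows$lower) > 0))
  expect_equal(nrow(sw$logor_curve), sum(ok & is.finite(log(
    sw$windows$or_point))))
  expect_error(sliding_window_or(load[1:40], y[1:40]), "reference")
})

test_that("supra-additive generation convexes the log-OR curve upward", {
  gen <- function(theta, seed) {
    # baseline chosen so the population prevalence stays near 50%:
    # E[sum beta g] = 50 * log(1.3) * 0.6 and E[(L - EL)^2] = Var(L) = 21
    b0 <- -(50 * log(1.3) * 0.6) - theta * 21
    cfg <- sim_config(n_cases = c(EA = 1500), n_controls = c(EA = 1500),
                      n_snps = 50, beta = rep(log(1.3), 50), theta = theta,
                      raf = matrix(0.3, 50, 1), b0 = b0, missing_rate = 0)
    ch <- simulate_cohort(cfg, seed = seed)
    w <- data.frame(snp_id = colnames(ch$genotypes),
                    risk_allele_is_coded = TRUE, gamma = 1)
    load <- compute_grs(ch$genotypes, w, "unweighted")$load
    nonlinearity_test(load, ch$samples$status)
  }
  set.seed(53)
  seeds <- sample.int(1e6, 8)
  quad_add <- sapply(seeds, function(s) gen(0, s)$quad_coef)
  quad_sup <- sapply(seeds, function(s) gen(0.05, s)$quad_coef)
  expect_gt(mean(quad_sup > 0), 0.8)
  expect_gt(mean(quad_sup), mean(quad_add))
  # curvature estimate increases monotonically in theta on average
  quad_mid <- sapply(seeds[1:4], function(s) gen(0.02, s)$quad_coef)
  expect_lt(mean(quad_add), mean(quad_mid))
  expect_lt(mean(quad_mid), mean(quad_sup[1:4]))
})

test_that("evaluate_grs matches the all-pairs concordance oracle", {
  set.seed(54)
  n <- 800
  load <- rbinom(n, 40, 0.4)
  y <- rbinom(n, 1, plogis(-2 + 0.12 * load))
  ev <- evaluate_grs(load, y, mode = "unweighted")
  f <- fit_logistic(y, cbind(load / 5))
  mu <- plogis(cbind(1, load / 5) %*% f$coef)
  expect_equal(ev$c_statistic_no_admix, cstat_oracle(as.vector(mu), y),
               tolerance = 1e-10)
  expect_equal(ev$per, "5 alleles")
  # per-5-allele OR: slope on load/5
  expect_equal(log(ev$or_point), unname(f$coef[2]), tolerance = 1e-8)
  # null load: c-statistic near 0.5 and CI covers 1
  y0 <- rbinom(n, 1, 0.5)
  ev0 <- evaluate_grs(load, y0, mode = "unweighted")
  expect_equal(ev0$c_statistic, 0.5, tolerance = 0.05)
  expect_true(ev0$ci_lo <= 1 && 1 <= ev0$ci_hi)
  # admixture covariates never lower the in-sample c-statistic
  Z <- cbind(rnorm(n))
  eva <- evaluate_grs(load, y, Z, mode = "unweighted")
  expect_gte(eva$c_statistic + 1e-10, eva$c_statistic_no_admix)
})

test_that("age-at-onset association reports Spearman r with regression P", {
  set.seed(55)
  n <- 1500
  load <- rnorm(n, 20, 4)
  age_null <- rnorm(n, 35, 10)
  r0 <- age_onset_association(load, age_null)
  expect_lt(abs(r0$spearman_r), 0.06)
  age_neg <- 35 - 0.8 * load + rnorm(n, 0, 6)
  r1 <- age_onset_association(load, age_neg)
  expect_lt(r1$spearman_r, 0)
  expect_lt(r1$p_regression, 1e-6)
  # rank invariance under monotone transform of load
  r2 <- age_onset_association(exp(load / 10), age_neg)
  expect_equal(r1$spearman_r, r2$spearman_r, tolerance = 1e-12)
  expect_error(age_onset_association(load[1:10], age_neg[1:10]), "fewer")
  expect_error(age_onset_association(load, rep(40, n)), "constant")
})
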