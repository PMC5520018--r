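test_that("HWE exact test matches the recurrence oracle and handles edge cases", {
  expect_equal(as.numeric(hwe_exact_test(0, 0, 100)), 1)
  expect_true(attr(hwe_exact_test(0, 0, 100), "monomorphic"))
  # balanced table at the modal heterozygote count has P = 1
  expect_equal(as.numeric(hwe_exact_test(25, 50, 25)),
               hwe_oracle_p(25, 50, 25), tolerance = 1e-12)
  # extreme heterozygote deficit: tiny exact P, matching enumeration
  p_def <- as.numeric(hwe_exact_test(50, 0, 50))
  expect_equal(p_def, hwe_oracle_p(50, 0, 50), tolerance = 1e-12)
  expect_lt(p_def, 1e-6)
  # spot grid against the oracle
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:150, 1)
    na <- sample(1:n, 1)
    hets <- seq.int(na %% 2, na, by = 2)
    h <- sample(hets, 1)
    hom_min <- (na - h) / 2; hom_maj <- n - h - hom_min
    expect_equal(as.numeric(hwe_exact_test(hom_min, h, hom_maj)),
                 hwe_oracle_p(hom_min, h, hom_maj), tolerance = 1e-12)
  }
})

test_that("SNP QC drops low call rate, differential missingness and low MAF", {
  set.seed(3)
  n <- 2000
  y <- rep(0:1, each = n / 2)
  g_clean <- rbinom(n, 2, 0.3)
  g_lowcr <- g_clean; g_lowcr[sample(n, 0.1 * n)] <- NA
  g_diff <- rbinom(n, 2, 0.3); g_diff[y == 1][sample(n / 2, 0.3 * n / 2)] <- NA
  g_rare <- rbinom(n, 2, 0.002)
  G <- cbind(clean = g_clean, lowcr = g_lowcr, diff = g_diff, rare = g_rare)
  qc <- run_snp_qc(G, y)
  expect_true("clean" %in% qc$keep)
  expect_false("lowcr" %in% qc$keep)
  expect_false("diff" %in% qc$keep)
  expect_false("rare" %in% qc$keep)
  expect_match(qc$report$reasons[qc$report$snp_id == "lowcr"], "call_rate")
  expect_match(qc$report$reasons[qc$report$snp_id == "diff"], "diff_missing")
  # a clean simulated panel retains essentially everything; the control-arm
  # HWE filter at P < 0.01 contributes a ~1% false-positive floor
  set.seed(4)
  kept_frac <- replicate(5, {
    G2 <- matrix(rbinom(800 * 60, 2, rep(runif(60, 0.1, 0.5), each = 800)),
                 nrow = 800, dimnames = list(NULL, paste0("s", 1:60)))
    length(run_snp_qc(G2, rep(0:1, 400))$keep) / 60
  })
  expect_gte(mean(kept_frac), 0.97)
})

test_that("sample QC keeps the higher-call-rate member of a duplicate pair", {
  set.seed(5)
  m <- 300
  base <- rbinom(m, 2, runif(m, 0.2, 0.5))
  G <- rbind(A = base, B = base, C = rbinom(m, 2, runif(m, 0.2, 0.5)),
             D = rbinom(m, 2, runif(m, 0.2, 0.5)))
  G["A", sample(m, 3)] <- NA   # call rate 0.99; B at 1.00 wins
  kept <- run_sample_qc(G)
  expect_true("B" %in% kept)
  expect_false("A" %in% kept)
  expect_true(all(c("C", "D") %in% kept))
  # a sample with 3% missing falls below the 98% call-rate bar
  G2 <- rbind(G, E = base)
  G2["E", sample(m, ceiling(0.03 * m))] <- NA
  expect_false("E" %in% run_sample_qc(G2))
  # unrelated samples are not flagged as duplicates
  set.seed(6)
  G3 <- matrix(rbinom(50 * 400, 2, rep(runif(400, 0.2, 0.5), each = 50)),
               nrow = 50, dimnames = list(paste0("U", 1:50), NULL))
  expect_length(run_sample_qc(G3), 50)
})

test_that("admixture factors are orthogonal, standardised, and rank-aware", {
  set.seed(7)
  P <- matrix(rgamma(900 * 3, 2), 900, 3)
  P <- P / rowSums(P)
  fs <- admixture_factors(P, 2)
  expect_equal(ncol(fs), 2)
  expect_lt(max(abs(cor(fs)[upper.tri(diag(2))])), 1e-8)
  expect_equal(unname(apply(fs, 2, sd)), c(1, 1), tolerance = 1e-8)
  # two-component simplex is rank one: a single factor carries everything
  P2 <- cbind(P[, 1], 1 - P[, 1], 0)
  expect_warning(f1 <- admixture_factors(P2, 2), "rank")
  expect_equal(ncol(f1), 1)
  expect_gt(abs(cor(f1[, 1], P2[, 1])), 0.9999)
})

test_that("varimax rotation leaves simple structure unchanged up to sign", {
  L <- rbind(c(0.9, 0), c(0.85, 0), c(0, 0.8), c(0, 0.95))
  rot <- stats::varimax(L, normalize = FALSE)
  aligned <- abs(rot$loadings)
  expect_equal(unclass(aligned), abs(L), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("LD pruning keeps independent SNPs and drops duplicated columns", {
  set.seed(8)
  n <- 500
  G <- sapply(1:10, function(i) rbinom(n, 2, 0.3))
  colnames(G) <- paste0("s", 1:10)
  expect_equal(ld_prune(G), colnames(G))   # independent: all retained
  G2 <- cbind(G, dup = G[, 3])
  kept <- ld_prune(G2)
  expect_true(xor("s3" %in% kept, "dup" %in% kept))
  u <- union_test_count(list(c("A", "B"), c("B", "C"), "C"))
  expect_equal(u$m, 3)
  expect_equal(u$threshold, 0.05 / 3)
})

test_that("genomic control matches the closed form and the chi-square null", {
  expect_equal(genomic_control(rep(qchisq(0.5, 1), 3), 500, 500)$lambda_1000,
               1)
  gc <- genomic_control(qchisq(0.5, 1) * 1.2, 2000, 2000)
  expect_equal(gc$lambda_gc, 1.2, tolerance = 1e-12)
  expect_equal(gc$lambda_1000, 1.10, tolerance = 1e-12)
  set.seed(9)
  gc_null <- genomic_control(rchisq(100000, 1), 1000, 1000)
  expect_equal(gc_null$lambda_gc, 1, tolerance = 0.01)
  expect_error(genomic_control(numeric(0), 10, 10), "no test statistics")
})
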