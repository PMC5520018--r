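#' Split a cohort into training and held-out test sets
#'
#' The test set is an exact random draw of `n_test_cases` cases and
#' `n_test_controls` controls; everything else trains. The partition is
#' disjoint and exhaustive.
#'
#' @param sample_ids character vector.
#' @param phenotype 0/1 aligned to `sample_ids`.
#' @param n_test_cases,n_test_controls test-set quotas (study default
#'   2,000/2,000).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_train_test <- function(sample_ids, phenotype, n_test_cases = 2000L,
                             n_test_controls = 2000L, seed = 1L) {
  cases <- sample_ids[phenotype == 1]
  ctrls <- sample_ids[phenotype == 0]
  if (length(cases) <= n_test_cases || length(ctrls) <= n_test_controls)
    stop("cohort too small for the requested test split")
  set.seed(child_seed(seed, "split"))
  test <- c(sample(cases, n_test_cases), sample(ctrls, n_test_controls))
  list(train = setdiff(sample_ids, test), test = test)
}

#' Select training SNPs and their risk-allele weights
#'
#' Re-runs the single-SNP association on the training samples, keeps SNPs with
#' BH-FDR adjusted P < `fdr`, thins them to stepwise-independent signals per
#' region, and returns |beta| weights with each SNP oriented so the weighted
#' allele is the risk allele (gamma > 0).
#'
#' @param genotypes training samples x SNPs matrix.
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @param regions factor/vector grouping SNP columns into regions for the
#'   stepwise thinning (NULL = one region).
#' @param fdr FDR threshold for the candidate set.
#' @param stepwise apply the regional stepwise thinning (TRUE).
#' @return data.frame snp_id/risk_allele_is_coded/gamma (empty if nothing
#'   passes; callers should then skip the load analysis).
#' @export
select_training_weights <- function(genotypes, phenotype, covariates = NULL,
                                    regions = NULL, fdr = 0.05,
                                    stepwise = TRUE) {
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes)
  res <- do.call(rbind, lapply(seq_len(ncol(genotypes)), function(j)
    test_snp(genotypes[, j], phenotype, covariates, snp_id = ids[j])))
  usable <- !is.na(res$p)
  res$fdr_adjusted_p <- NA_real_
  res$fdr_adjusted_p[usable] <- stats::p.adjust(res$p[usable], method = "BH")
  cand <- res$snp_id[usable & res$fdr_adjusted_p < fdr]
  if (!length(cand))
    return(data.frame(snp_id = character(), risk_allele_is_coded = logical(),
                      gamma = numeric(), stringsAsFactors = FALSE))
  if (stepwise) {
    if (is.null(regions)) regions <- rep(1L, ncol(genotypes))
    names(regions) <- ids
    kept <- unlist(lapply(split(cand, regions[cand]), function(snps) {
      if (length(snps) == 1) return(snps)
      regional_stepwise(genotypes[, snps, drop = FALSE], phenotype,
                        covariates, p_enter = fdr, p_exit = fdr)$selected
    }))
    cand <- intersect(cand, kept)
  }
  sel <- res[match(cand, res$snp_id), ]
  data.frame(snp_id = sel$snp_id,
             risk_allele_is_coded = sel$beta > 0,
             gamma = abs(sel$beta), stringsAsFactors = FALSE)
}

#' Per-sample genetic risk-allele load
#'
#' `GRS_i = sum_k gamma_k RA_ik` with `RA` the risk-allele count (0/1/2);
#' unweighted mode fixes all gamma at 1 so the load is the risk-allele count.
#' Genotypes coded on the non-risk allele are flipped (`RA = 2 - g`); a
#' missing genotype contributes its cohort-frequency expectation `2 * RAF`.
#'
#' @param genotypes samples x SNPs matrix (coded-allele counts).
#' @param weights data.frame from [select_training_weights()].
#' @param mode `"weighted"` or `"unweighted"`.
#' @return data.frame sample_id/load/n_snps; weight SNPs absent from the
#'   matrix are dropped with a warning.
#' @export
compute_grs <- function(genotypes, weights, mode = c("weighted",
                                                     "unweighted")) {
  mode <- match.arg(mode)
  genotypes <- as.matrix(genotypes)
  present <- weights$snp_id %in% colnames(genotypes)
  if (any(!present)) {
    warning(sum(!present), " weight SNPs absent from genotype matrix, dropped")
    weights <- weights[present, , drop = FALSE]
  }
  if (!nrow(weights)) stop("no weight SNPs available")
  G <- genotypes[, weights$snp_id, drop = FALSE]
  RA <- G
  flip <- !weights$risk_allele_is_coded
  RA[, flip] <- 2 - RA[, flip]
  raf <- colMeans(RA, na.rm = TRUE) / 2
  for (j in seq_len(ncol(RA))) {
    miss <- is.na(RA[, j])
    if (any(miss)) RA[miss, j] <- 2 * raf[j]
  }
  g <- if (mode == "weighted") weights$gamma else rep(1, nrow(weights))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))
  data.frame(sample_id = ids, load = as.vector(RA %*% g),
             n_snps = nrow(weights), stringsAsFactors = FALSE)
}

#' Sliding-window odds ratios of genetic load
#'
#' Samples whose load falls in the lowest `ref_quantile` of the load
#' distribution form the fixed reference; each window `[L, L + width]`
#' (stepping by `step`) is contrasted with the reference in an
#' admixture-adjusted logistic model (window membership vs reference).
#' Windows overlapping the reference have the overlap removed; windows with
#' fewer than `min_window_n` samples are skipped with a flag. A companion
#' log(OR)-vs-midpoint series supports curvature inspection on the logit
#' scale.
#'
#' @param loads numeric per-sample load.
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @param window_width window width on the load scale (study defaults: 20
#'   unweighted counts, 4 weighted units).
#' @param step window advance (default 1 for counts; for weighted loads the
#'   smallest distinct weight, fallback 0.05).
#' @param ref_quantile reference fraction of the load distribution.
#' @param min_window_n minimum window occupancy.
#' @param min_ref_n minimum reference size.
#' @return list with `windows` (data.frame) and `logor_curve`.
#' @export
sliding_window_or <- function(loads, phenotype, covariates = NULL,
                              window_width = 20, step = 1,
                              ref_quantile = 0.10, min_window_n = 20L,
                              min_ref_n = 50L) {
  stopifnot(length(loads) == length(phenotype))
  ref_cut <- stats::quantile(loads, ref_quantile)
  ref <- which(loads <= ref_cut)
  if (length(ref) < min_ref_n)
    stop("reference decile holds fewer than ", min_ref_n, " samples")
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  starts <- seq(min(loads), max(loads) - window_width, by = step)
  rows <- lapply(starts, function(lo) {
    hi <- lo + window_width
    win <- which(loads >= lo & loads <= hi)
    win <- setdiff(win, ref)
    base <- data.frame(lower = lo, upper = hi, n_in_window = length(win),
                       or_point = NA_real_, ci_lo = NA_real_,
                       ci_hi = NA_real_, p = NA_real_, skipped = TRUE,
                       stringsAsFactors = FALSE)
    if (length(win) < min_window_n) return(base)
    idx <- c(ref, win)
    memb <- as.numeric(idx %in% win)
    y <- phenotype[idx]
    if (length(unique(y)) < 2) return(base)
    X <- if (is.null(Z)) cbind(win = memb) else
      cbind(win = memb, Z[idx, , drop = FALSE])
    f <- tryCatch(fit_logistic(y, X), error = function(e) NULL)
    if (is.null(f)) return(base)
    b <- unname(f$coef[2]); se <- unname(f$se[2])
    base$or_point <- exp(b); base$ci_lo <- exp(b - 1.959964 * se)
    base$ci_hi <- exp(b + 1.959964 * se); base$p <- wald_p(b, se)
    base$skipped <- FALSE
    base
  })
  windows <- do.call(rbind, rows)
  usable <- !windows$skipped & is.finite(log(windows$or_point))
  curve <- data.frame(midpoint = (windows$lower + windows$upper) / 2,
                      log_or = log(windows$or_point))[usable, ]
  list(windows = windows, logor_curve = curve, reference_cut = ref_cut,
       n_reference = length(ref))
}

#' Test for departure from linearity of risk on the logit scale
#'
#' Primary test: 1-df LRT of the logistic model in centred load plus centred
#' load squared against load alone. A secondary variant tests the interaction
#' of a top-quartile indicator with load, probing a greater-than-additive
#' effect confined to the highest quarter of the load range.
#'
#' @param loads per-sample load (variance > 0).
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @return list with `p_quadratic`, `quad_coef`, `p_top_quarter`,
#'   `top_quarter_coef`.
#' @export
nonlinearity_test <- function(loads, phenotype, covariates = NULL) {
  if (stats::sd(loads) == 0) stop("degenerate (constant) load")
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  cl <- loads - mean(loads)
  X0 <- cbind(load = cl); X1 <- cbind(load = cl, load2 = cl^2)
  if (!is.null(Z)) { X0 <- cbind(X0, Z); X1 <- cbind(X1, Z) }
  f0 <- fit_logistic(phenotype, X0)
  f1 <- fit_logistic(phenotype, X1)
  lrt <- max(2 * (f1$loglik - f0$loglik), 0)
  # top-quartile variant: indicator for the highest quarter of the range x load
  q <- as.numeric(loads > stats::quantile(loads, 0.75))
  Xq <- cbind(load = cl, top = q, top_x_load = q * cl)
  if (!is.null(Z)) Xq <- cbind(Xq, Z)
  fq <- tryCatch(fit_logistic(phenotype, Xq), error = function(e) NULL)
  list(p_quadratic = stats::pchisq(lrt, 1, lower.tail = FALSE),
       quad_coef = unname(f1$coef[["load2"]]),
       p_top_quarter = if (is.null(fq)) NA_real_ else
         wald_p(fq$coef[["top_x_load"]], fq$se[["top_x_load"]]),
       top_quarter_coef = if (is.null(fq)) NA_real_ else
         unname(fq$coef[["top_x_load"]]))
}

concordance <- function(score, y) {
  # rank-based c-statistic (AUC); O(n log n)
  r <- rank(score)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summary evaluation of a genetic load
#'
#' Logistic slope of status on load (per 5 alleles for the unweighted load,
#' per unit for the weighted load) with admixture covariates, plus the
#' c-statistic (concordance of fitted probabilities) for models with and
#' without the admixture factors.
#'
#' @param loads per-sample load.
#' @param phenotype 0/1 vector.
#' @param covariates admixture factor matrix or NULL.
#' @param mode `"unweighted"` (slope per 5 alleles) or `"weighted"`.
#' @return one-row data.frame with or/ci/p and the two c-statistics.
#' @export
evaluate_grs <- function(loads, phenotype, covariates = NULL,
                         mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  x <- if (mode == "unweighted") loads / 5 else loads
  X1 <- if (is.null(covariates)) cbind(load = x) else
    cbind(load = x, as.matrix(covariates))
  f1 <- fit_logistic(phenotype, X1)
  mu1 <- stats::plogis(cbind(1, X1) %*% f1$coef)
  f0 <- fit_logistic(phenotype, cbind(load = x))
  mu0 <- stats::plogis(cbind(1, x) %*% f0$coef)
  b <- unname(f1$coef[2]); se <- unname(f1$se[2])
  data.frame(mode = mode, or_point = exp(b),
             ci_lo = exp(b - 1.959964 * se), ci_hi = exp(b + 1.959964 * se),
             p = wald_p(b, se),
             c_statistic = concordance(as.vector(mu1), phenotype),
             c_statistic_no_admix = concordance(as.vector(mu0), phenotype),
             per = if (mode == "unweighted") "5 alleles" else "1 unit",
             stringsAsFactors = FALSE)
}

#' Association of genetic load with age at diagnosis (cases only)
#'
#' Reports the Spearman rank correlation of load with age, with the P-value
#' taken from the admixture-adjusted linear regression of age on load.
#'
#' @param loads per-case load.
#' @param age age at diagnosis.
#' @param covariates admixture factors for the regression, or NULL.
#' @param min_n minimum number of cases with ages.
#' @return list with spearman_r, p_regression, slope, n.
#' @export
age_onset_association <- function(loads, age, covariates = NULL,
                                  min_n = 30L) {
  ok <- !is.na(loads) & !is.na(age)
  if (sum(ok) < min_n) stop("fewer than ", min_n, " cases with ages")
  l <- loads[ok]; a <- age[ok]
  if (stats::sd(a) == 0) stop("constant age")
  r <- stats::cor(l, a, method = "spearman")
  dat <- if (is.null(covariates)) data.frame(age = a, load = l) else
    data.frame(age = a, load = l,
               as.matrix(covariates)[ok, , drop = FALSE])
  fit <- stats::lm(age ~ ., data = dat)
  sm <- summary(fit)$coefficients
  list(spearman_r = r, p_regression = sm["load", 4],
       slope = sm["load", 1], n = sum(ok))
}
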