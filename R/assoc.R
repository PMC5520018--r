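#' Logistic maximum-likelihood fit
#'
#' Fits by iteratively reweighted least squares (via `stats::glm.fit`) and
#' post-checks convergence of the score; (quasi-)complete separation is
#' detected from diverging coefficients with degenerate fitted probabilities
#' and flagged with an infinite-beta sentinel rather than returned silently.
#'
#' @param y binary response (0/1).
#' @param X design matrix, intercept included by the caller via
#'   `add_intercept`.
#' @param add_intercept prepend a column of ones (default TRUE).
#' @return list with `coef`, `se`, `vcov`, `loglik`, `converged`, `separation`.
#' @export
fit_logistic <- function(y, X, add_intercept = TRUE) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("response has a single class")
  X <- as.matrix(X)
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  # drop aliased columns so the fit is full rank
  qrX <- qr(X)
  aliased <- rep(FALSE, ncol(X))
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased[-keep] <- TRUE
    X <- X[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-12, maxit = 50)))
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  score <- crossprod(X, y - mu)
  converged <- fit$converged && max(abs(score)) < 1e-6
  separation <- any(abs(fit$coefficients) > 15) &&
    (min(mu) < 1e-8 || max(mu) > 1 - 1e-8)
  XtWX <- crossprod(X * w, X)
  vc <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  co <- fit$coefficients
  se <- sqrt(diag(vc))
  if (separation) {
    big <- abs(co) > 15
    co[big] <- sign(co[big]) * Inf
    se[big] <- Inf
  }
  names(se) <- names(co) <- colnames(X)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coef = co, se = se, vcov = vc, loglik = ll,
       converged = converged, separation = separation,
       aliased = aliased, n = length(y))
}

wald_p <- function(beta, se) {
  ifelse(is.finite(beta) & is.finite(se) & se > 0,
         2 * stats::pnorm(abs(beta / se), lower.tail = FALSE), NA_real_)
}

#' Single-SNP association with genetic-model selection
#'
#' Primary inference uses the additive genetic model unless the 1-df
#' lack-of-fit likelihood-ratio test (full genotypic vs additive) is
#' significant at `lof_alpha`, in which case the most significant of the
#' dominant, additive and recessive models is reported. The additive and
#' recessive models are only computed with at least `min_hom_additive` and
#' `min_hom_recessive` minor-allele homozygotes respectively; with too few,
#' the dominant model is reported with the reason recorded. Samples with a
#' missing genotype are dropped for that SNP.
#'
#' @param genotype 0/1/2 vector (NA = missing), counted in any allele; the
#'   minor allele is determined internally and results are reported on the
#'   coded (input) allele scale.
#' @param phenotype 0/1 vector.
#' @param covariates matrix of adjustment covariates (e.g. admixture factors)
#'   or NULL.
#' @param snp_id label carried into the result.
#' @param lof_alpha lack-of-fit significance level.
#' @param min_hom_additive,min_hom_recessive homozygote-count gates.
#' @return one-row data.frame: `p` is the reported (selected-model) P while
#'   `p_additive` always carries the primary additive-model P when that model
#'   was computable; the additive P is the calibrated one under the null
#'   (model selection conditions on the lack-of-fit outcome and so trades a
#'   small null inflation for power against non-additive effects).
#' @export
test_snp <- function(genotype, phenotype, covariates = NULL,
                     snp_id = "snp", lof_alpha = 0.05,
                     min_hom_additive = 10L, min_hom_recessive = 30L) {
  ok <- !is.na(genotype) & !is.na(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  g <- genotype[ok]; y <- phenotype[ok]
  Z <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
  n <- length(g)
  fail <- function(reason) data.frame(
    snp_id = snp_id, model_used = NA_character_, beta = NA_real_,
    se = NA_real_, or_point = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
    p = NA_real_, p_additive = NA_real_, lack_of_fit_p = NA_real_,
    n_used = n, note = reason, stringsAsFactors = FALSE)
  if (n == 0 || length(unique(y)) < 2) return(fail("degenerate sample"))
  if (length(unique(g)) < 2) return(fail("monomorphic"))
  # orient to the minor allele for the homozygote gates
  flip <- mean(g) / 2 > 0.5
  gm <- if (flip) 2 - g else g
  n_hom_minor <- sum(gm == 2)

  design <- function(cols) if (is.null(Z)) cols else cbind(cols, Z)
  fit1 <- function(cols) tryCatch(fit_logistic(y, design(cols)),
                                  error = function(e) NULL)
  fits <- list()
  models_ok <- c(dominant = TRUE,
                 additive = n_hom_minor >= min_hom_additive,
                 recessive = n_hom_minor >= min_hom_recessive)
  fits$dominant <- fit1(cbind(g_dom = as.numeric(gm > 0)))
  if (models_ok["additive"]) fits$additive <- fit1(cbind(g_add = gm))
  if (models_ok["recessive"]) fits$recessive <- fit1(cbind(g_rec =
                                                             as.numeric(gm == 2)))
  classes <- sort(unique(gm))
  lof_p <- NA_real_
  if (models_ok["additive"] && length(classes) == 3 && !is.null(fits$additive)) {
    fit_gen <- fit1(cbind(g_het = as.numeric(gm == 1),
                          g_hom = as.numeric(gm == 2)))
    if (!is.null(fit_gen) && !is.null(fits$additive)) {
      lrt <- 2 * (fit_gen$loglik - fits$additive$loglik)
      lof_p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
    }
  }
  pvals <- vapply(fits, function(f)
    if (is.null(f)) NA_real_ else wald_p(f$coef[2], f$se[2]), numeric(1))
  note <- ""
  if (!models_ok["additive"]) {
    model <- "dominant"
    note <- sprintf("additive/recessive not computed (%d minor homozygotes)",
                    n_hom_minor)
  } else if (is.na(lof_p) || lof_p >= lof_alpha) {
    model <- "additive"
  } else {
    cand <- names(pvals)[!is.na(pvals)]
    model <- cand[which.min(pvals[cand])]
    note <- "lack-of-fit to additive"
  }
  f <- fits[[model]]
  if (is.null(f)) return(fail("fit failed"))
  beta <- unname(f$coef[2]); se <- unname(f$se[2])
  if (flip) beta <- -beta  # report on the coded-allele scale
  data.frame(snp_id = snp_id, model_used = model, beta = beta, se = se,
             or_point = exp(beta), ci_lo = exp(beta - 1.959964 * se),
             ci_hi = exp(beta + 1.959964 * se), p = pvals[[model]],
             p_additive = if ("additive" %in% names(pvals))
               pvals[["additive"]] else NA_real_,
             lack_of_fit_p = lof_p, n_used = n, note = note,
             stringsAsFactors = FALSE)
}

#' Tiered significance with Benjamini-Hochberg adjustment
#'
#' Tier 1: P < `tier1`; Tier 2: otherwise P < `tier2`; Tier 3: otherwise
#' BH-adjusted P < `fdr`. Both the 0.05 and 0.01 FDR significance columns are
#' reported; the tier label uses `fdr`.
#'
#' @param p vector of raw two-sided P-values.
#' @param tier1,tier2,fdr thresholds.
#' @return data.frame with p, fdr_adjusted_p, tier, fdr_sig_05, fdr_sig_01.
#' @export
assign_tiers <- function(p, tier1 = 5e-8, tier2 = 1e-6, fdr = 0.05) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(p, method = "BH")
  tier <- rep("none", length(p))
  tier[adj < fdr] <- "3"
  tier[p < tier2] <- "2"
  tier[p < tier1] <- "1"
  data.frame(p = p, fdr_adjusted_p = adj, tier = tier,
             fdr_sig_05 = adj < 0.05, fdr_sig_01 = adj < 0.01,
             stringsAsFactors = FALSE)
}

#' Regional stepwise model selection
#'
#' Forward selection with backward elimination over the SNPs of a region
#' (additive coding): at each step the candidate with the smallest conditional
#' Wald P enters if below `p_enter`; any selected SNP whose conditional P
#' rises above `p_exit` is removed. Candidates collinear with the current
#' model are skipped with a flag; ties are broken by smallest genomic
#' position. A visited-set guard ensures termination.
#'
#' @param genotypes samples x SNPs matrix for the region.
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @param positions genomic positions for tie-breaks (defaults to column
#'   index).
#' @param p_enter,p_exit entry and exit criteria.
#' @return list with `selected` (SNP ids), `conditional` (data.frame of
#'   conditional estimates) and `skipped_collinear`.
#' @export
regional_stepwise <- function(genotypes, phenotype, covariates = NULL,
                              positions = NULL, p_enter = 0.001,
                              p_exit = 0.001) {
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  colnames(genotypes) <- ids
  if (is.null(positions)) positions <- seq_len(ncol(genotypes))
  # complete cases across the region keep the deviance bookkeeping monotone
  ok <- stats::complete.cases(genotypes) & !is.na(phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
  }
  G <- genotypes[ok, , drop = FALSE]; y <- phenotype[ok]
  Z <- if (is.null(covariates)) NULL else covariates[ok, , drop = FALSE]
  selected <- character(0)
  skipped <- character(0)
  visited <- character(0)
  cond_p <- function(model_ids) {
    X <- G[, model_ids, drop = FALSE]
    if (!is.null(Z)) X <- cbind(X, Z)
    f <- tryCatch(fit_logistic(y, X), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    idx <- seq_along(model_ids) + 1L
    data.frame(snp_id = model_ids, beta = unname(f$coef[idx]),
               se = unname(f$se[idx]),
               p = wald_p(unname(f$coef[idx]), unname(f$se[idx])),
               stringsAsFactors = FALSE)
  }
  repeat {
    state <- paste(sort(selected), collapse = ",")
    if (state %in% visited) break
    visited <- c(visited, state)
    # forward
    cands <- setdiff(ids, c(selected, skipped))
    best <- NULL; best_p <- Inf; best_pos <- Inf
    for (s in cands) {
      if (length(selected)) {
        r2 <- suppressWarnings(
          summary(stats::lm(G[, s] ~ G[, selected, drop = FALSE]))$r.squared)
        if (!is.na(r2) && r2 > 0.999) { skipped <- c(skipped, s); next }
      }
      ct <- cond_p(c(selected, s))
      if (is.null(ct)) { skipped <- c(skipped, s); next }
      ps <- ct$p[ct$snp_id == s]
      if (is.na(ps)) next
      pos_s <- positions[match(s, ids)]
      if (ps < best_p - 1e-15 ||
          (abs(ps - best_p) <= 1e-15 && pos_s < best_pos)) {
        best <- s; best_p <- ps; best_pos <- pos_s
      }
    }
    changed <- FALSE
    if (!is.null(best) && best_p < p_enter) {
      selected <- c(selected, best); changed <- TRUE
    }
    # backward
    if (length(selected) > 1) {
      ct <- cond_p(selected)
      worst <- ct$snp_id[which.max(ct$p)]
      if (max(ct$p, na.rm = TRUE) > p_exit) {
        selected <- setdiff(selected, worst); changed <- TRUE
      }
    }
    if (!changed) break
  }
  conditional <- if (length(selected)) cond_p(selected) else
    data.frame(snp_id = character(), beta = numeric(), se = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  list(selected = selected, conditional = conditional,
       skipped_collinear = skipped)
}

#' Pairwise SNP-SNP and case-only sex interaction scans
#'
#' `snp_snp`: for each candidate pair, the model holds covariates, both SNPs
#' and their centred cross-product; the product term is tested by a 1-df
#' likelihood-ratio test. `sex_caseonly`: among cases only, sex is the
#' outcome and each SNP (plus covariates) the predictor, tested by a 1-df
#' LRT.
#'
#' @param mode `"snp_snp"` or `"sex_caseonly"`.
#' @param genotypes samples x candidate-SNPs matrix.
#' @param phenotype 0/1 (ignored in sex_caseonly beyond case selection).
#' @param sex "F"/"M" or 0/1 vector (sex_caseonly mode).
#' @param covariates adjustment matrix or NULL.
#' @return data.frame of tests with Bonferroni and BH-FDR columns.
#' @export
interaction_scan <- function(mode = c("snp_snp", "sex_caseonly"),
                             genotypes, phenotype, sex = NULL,
                             covariates = NULL) {
  mode <- match.arg(mode)
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  if (mode == "snp_snp") {
    pairs <- utils::combn(seq_len(ncol(genotypes)), 2)
    res <- apply(pairs, 2, function(pr) {
      g1 <- genotypes[, pr[1]]; g2 <- genotypes[, pr[2]]
      ok <- !is.na(g1) & !is.na(g2) & !is.na(phenotype)
      Z <- if (is.null(covariates)) NULL else
        as.matrix(covariates)[ok, , drop = FALSE]
      g1 <- g1[ok]; g2 <- g2[ok]; y <- phenotype[ok]
      cp <- (g1 - mean(g1)) * (g2 - mean(g2))
      X0 <- cbind(g1 = g1, g2 = g2); X1 <- cbind(X0, cp = cp)
      if (!is.null(Z)) { X0 <- cbind(X0, Z); X1 <- cbind(X1, Z) }
      f1 <- tryCatch(fit_logistic(y, X1), error = function(e) NULL)
      f0 <- tryCatch(fit_logistic(y, X0), error = function(e) NULL)
      if (is.null(f0) || is.null(f1) || f1$aliased[4])
        return(c(NA_real_, NA_real_))
      lrt <- max(2 * (f1$loglik - f0$loglik), 0)
      c(lrt, stats::pchisq(lrt, 1, lower.tail = FALSE))
    })
    out <- data.frame(snp1 = ids[pairs[1, ]], snp2 = ids[pairs[2, ]],
                      lrt = res[1, ], p = res[2, ], stringsAsFactors = FALSE)
  } else {
    stopifnot(!is.null(sex))
    s <- if (is.numeric(sex)) sex else as.numeric(sex == "F")
    cases <- which(phenotype == 1)
    out <- do.call(rbind, lapply(seq_len(ncol(genotypes)), function(j) {
      g <- genotypes[cases, j]; y <- s[cases]
      ok <- !is.na(g)
      Z <- if (is.null(covariates)) NULL else
        as.matrix(covariates)[cases, , drop = FALSE][ok, , drop = FALSE]
      g <- g[ok]; y <- y[ok]
      f1 <- tryCatch(fit_logistic(y, if (is.null(Z)) cbind(g = g) else
        cbind(g = g, Z)), error = function(e) NULL)
      f0 <- tryCatch(fit_logistic(y, if (is.null(Z))
        matrix(numeric(0), nrow = length(y), ncol = 0) else Z),
        error = function(e) NULL)
      if (is.null(f0) || is.null(f1))
        return(data.frame(snp = ids[j], lrt = NA_real_, p = NA_real_))
      lrt <- max(2 * (f1$loglik - f0$loglik), 0)
      data.frame(snp = ids[j], lrt = lrt,
                 p = stats::pchisq(lrt, 1, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  out$p_bonferroni <- pmin(out$p * sum(!is.na(out$p)), 1)
  out$fdr_adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Chromosome-X association: sex-stratified analysis combined by
#' inverse-normal meta-analysis
#'
#' Female genotypes are analysed as 0/1/2; males are hemizygous and coded
#' 0/2 (dosage convention, recorded in the output). Stratum results are
#' combined with weights sqrt(stratum N).
#'
#' @param genotype X-chromosome genotype vector (males may be supplied as
#'   0/1 and are rescaled to 0/2).
#' @param phenotype 0/1 vector.
#' @param sex "F"/"M" vector.
#' @param covariates adjustment matrix or NULL.
#' @param snp_id label.
#' @return list with `strata` (per-sex assoc rows), `combined` (meta result or
#'   single-stratum passthrough) and `male_coding`.
#' @export
chrx_association <- function(genotype, phenotype, sex, covariates = NULL,
                             snp_id = "snpX") {
  g <- genotype
  male <- sex == "M"
  g[male & g == 1] <- 2  # hemizygote dosage convention
  strata <- list()
  for (s in c("F", "M")) {
    idx <- which(sex == s)
    if (length(idx) < 10 || length(unique(phenotype[idx])) < 2) next
    Z <- if (is.null(covariates)) NULL else
      as.matrix(covariates)[idx, , drop = FALSE]
    row <- test_snp(g[idx], phenotype[idx], Z,
                    snp_id = paste0(snp_id, "_", s))
    row$stratum <- s; row$n_stratum <- length(idx)
    strata[[s]] <- row
  }
  strata_df <- do.call(rbind, strata)
  usable <- !is.na(strata_df$p)
  if (sum(usable) >= 2) {
    inp <- meta_input(cohort = strata_df$stratum[usable],
                      p = strata_df$p[usable],
                      direction = sign(strata_df$beta[usable]),
                      n = strata_df$n_stratum[usable])
    combined <- inverse_normal_meta(inp)
  } else if (sum(usable) == 1) {
    one <- strata_df[usable, ]
    combined <- list(z_combined = sign(one$beta) *
                       stats::qnorm(one$p / 2, lower.tail = FALSE),
                     p_combined = one$p, single_stratum = one$stratum)
  } else combined <- NULL
  list(strata = strata_df, combined = combined, male_coding = "0/2")
}

#' Expected number of discoveries at a significance level
#'
#' For each SNP the two-sided Wald power at `alpha` is computed from the
#' asymptotic variance of the log allelic odds ratio under expected allele
#' counts (`1/a + 1/b + 1/c + 1/d`); the expectation is the sum of powers.
#' `raf` is the control risk-allele frequency; the case frequency is derived
#' from the odds ratio.
#'
#' @param or per-SNP odds ratios (> 0).
#' @param raf per-SNP control risk-allele frequencies in (0,1).
#' @param n_cases,n_controls study sizes.
#' @param alpha two-sided significance level.
#' @return list with `expected` (sum of powers) and `power` (per SNP).
#' @export
expected_discoveries <- function(or, raf, n_cases, n_controls, alpha) {
  stopifnot(all(or > 0), all(raf > 0 & raf < 1))
  beta <- log(or)
  odds_ctrl <- raf / (1 - raf)
  p_case <- or * odds_ctrl / (1 + or * odds_ctrl)
  a <- 2 * n_cases * p_case; b <- 2 * n_cases * (1 - p_case)
  c <- 2 * n_controls * raf; d <- 2 * n_controls * (1 - raf)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(alpha / 2, lower.tail = FALSE)
  power <- stats::pnorm(-z + abs(beta) / se) +
    stats::pnorm(-z - abs(beta) / se)
  list(expected = sum(power), power = power)
}
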