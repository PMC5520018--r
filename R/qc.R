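#' Quality-control thresholds
#'
#' Defaults follow standard dense-array case-control practice: SNP call rate
#' >= 0.95, sample call rate >= 0.98, differential missingness P < 0.05,
#' Hardy-Weinberg exact P < 1e-6 in cases and < 0.01 in controls, MAF >= 0.01,
#' LD pruning at r^2 < 0.2, duplicate screening at IBS concordance > 0.9.
#'
#' @param snp_call_rate,sample_call_rate,diff_missing_p,hwe_p_cases,hwe_p_controls,maf_min,ld_r2_max,duplicate_ibs thresholds, all in (0, 1].
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(snp_call_rate = 0.95, sample_call_rate = 0.98,
                          diff_missing_p = 0.05, hwe_p_cases = 1e-6,
                          hwe_p_controls = 0.01, maf_min = 0.01,
                          ld_r2_max = 0.2, duplicate_ibs = 0.9) {
  th <- list(snp_call_rate = snp_call_rate, sample_call_rate = sample_call_rate,
             diff_missing_p = diff_missing_p, hwe_p_cases = hwe_p_cases,
             hwe_p_controls = hwe_p_controls, maf_min = maf_min,
             ld_r2_max = ld_r2_max, duplicate_ibs = duplicate_ibs)
  stopifnot(all(unlist(th) > 0), all(unlist(th) <= 1))
  structure(th, class = "qc_thresholds")
}

#' Exact conditional Hardy-Weinberg test
#'
#' Conditional on the observed allele counts, the probability of each possible
#' heterozygote count is computed in closed form (log-gamma factorials); the
#' P-value is the sum of probabilities of all heterozygote counts no more
#' probable than the observed one. No mid-P correction is applied.
#'
#' @param n_hom_minor,n_het,n_hom_major genotype counts.
#' @return P-value; attribute `monomorphic` flags the degenerate case (P = 1).
#' @export
hwe_exact_test <- function(n_hom_minor, n_het, n_hom_major) {
  stopifnot(n_hom_minor >= 0, n_het >= 0, n_hom_major >= 0)
  n <- n_hom_minor + n_het + n_hom_major
  if (n == 0) stop("empty genotype table")
  na <- 2 * n_hom_minor + n_het           # minor allele count
  if (na > n) { # ensure 'na' really is the minor allele count
    na <- 2 * n - na
  }
  if (na == 0 || na == 2 * n) {
    return(structure(1, monomorphic = TRUE))
  }
  hets <- seq.int(na %% 2, na, by = 2)    # feasible heterozygote counts
  hom_min <- (na - hets) / 2
  hom_maj <- n - hets - hom_min
  logp <- lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(hets + 1) -
    lgamma(hom_maj + 1) + hets * log(2) +
    lgamma(na + 1) + lgamma(2 * n - na + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("inconsistent genotype counts")
  # tolerance guards ties against floating-point noise
  structure(min(1, sum(p[p <= p[obs] * (1 + 1e-10)])), monomorphic = FALSE)
}

#' Per-SNP quality control
#'
#' Drops SNPs failing overall call rate, case/control differential missingness
#' (Pearson 2x2 chi-square, no continuity correction), the exact
#' Hardy-Weinberg test at separate case and control thresholds, or minor
#' allele frequency. A SNP may fail several filters; all reasons are recorded.
#'
#' @param genotypes samples x SNPs matrix, 0/1/2 with NA missing.
#' @param phenotype 0/1 vector aligned to rows.
#' @param thresholds a [qc_thresholds()].
#' @return list with `keep` (SNP ids) and `report` (per-SNP metrics + reasons).
#' @export
run_snp_qc <- function(genotypes, phenotype, thresholds = qc_thresholds()) {
  stopifnot(length(phenotype) == nrow(genotypes),
            all(phenotype %in% c(0, 1)))
  m <- ncol(genotypes)
  cr <- 1 - colMeans(is.na(genotypes))
  miss_case <- colMeans(is.na(genotypes[phenotype == 1, , drop = FALSE]))
  miss_ctrl <- colMeans(is.na(genotypes[phenotype == 0, , drop = FALSE]))
  n_case <- sum(phenotype == 1); n_ctrl <- sum(phenotype == 0)
  diffmiss_p <- vapply(seq_len(m), function(j) {
    a <- miss_case[j] * n_case; b <- n_case - a
    c <- miss_ctrl[j] * n_ctrl; d <- n_ctrl - c
    if (a + c == 0) return(1)
    tab <- round(matrix(c(a, b, c, d), 2))
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  hwe_p <- function(rows, j) {
    g <- genotypes[rows, j]; g <- g[!is.na(g)]
    if (!length(g)) return(1)
    p <- mean(g) / 2
    if (p > 0.5) g <- 2 - g   # recode to minor allele
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }
  hwe_case <- vapply(seq_len(m), function(j) hwe_p(phenotype == 1, j),
                     numeric(1))
  hwe_ctrl <- vapply(seq_len(m), function(j) hwe_p(phenotype == 0, j),
                     numeric(1))
  af <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail <- cbind(
    call_rate = cr < thresholds$snp_call_rate,
    diff_missing = diffmiss_p < thresholds$diff_missing_p,
    hwe_cases = hwe_case < thresholds$hwe_p_cases,
    hwe_controls = hwe_ctrl < thresholds$hwe_p_controls,
    maf = is.na(maf) | maf < thresholds$maf_min)
  reasons <- apply(fail, 1, function(f)
    paste(colnames(fail)[f], collapse = ";"))
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  report <- data.frame(snp_id = ids, call_rate = cr,
                       diff_missing_p = diffmiss_p, hwe_p_cases = hwe_case,
                       hwe_p_controls = hwe_ctrl, maf = maf,
                       pass = reasons == "", reasons = reasons,
                       stringsAsFactors = FALSE)
  keep <- ids[report$pass]
  if (!length(keep))
    stop("all SNPs failed QC; dominant failure: ",
         names(sort(colSums(fail), decreasing = TRUE))[1])
  list(keep = keep, report = report)
}

#' Per-sample quality control
#'
#' Drops samples below the call-rate threshold, then screens remaining pairs
#' for duplicates/first-degree relatives by identity-by-state concordance on
#' a SNP subset; of each flagged pair the member with the higher call rate is
#' retained.
#'
#' @param genotypes samples x SNPs matrix.
#' @param thresholds a [qc_thresholds()].
#' @param ibs_snps number of SNPs used for the IBS screen (subsampled for
#'   speed; concordance is the fraction of identical calls among pairwise
#'   complete genotypes).
#' @return character vector of retained sample ids.
#' @export
run_sample_qc <- function(genotypes, thresholds = qc_thresholds(),
                          ibs_snps = 200L) {
  stopifnot(nrow(genotypes) >= 2)
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(genotypes)))
  cr <- 1 - rowMeans(is.na(genotypes))
  keep <- cr >= thresholds$sample_call_rate
  g <- genotypes[keep, , drop = FALSE]
  ids_k <- ids[keep]; cr_k <- cr[keep]
  cols <- seq_len(ncol(g))
  if (length(cols) > ibs_snps)
    cols <- round(seq(1, length(cols), length.out = ibs_snps))
  gs <- g[, cols, drop = FALSE]
  obs <- !is.na(gs)
  # matches via indicator cross-products; complete pairs likewise
  match_n <- matrix(0, nrow(gs), nrow(gs))
  for (v in 0:2) {
    iv <- (gs == v) & obs
    storage.mode(iv) <- "double"
    match_n <- match_n + tcrossprod(iv)
  }
  comp_n <- tcrossprod(matrix(as.double(obs), nrow(gs)))
  ibs <- match_n / pmax(comp_n, 1)
  drop <- rep(FALSE, nrow(gs))
  pairs <- which(upper.tri(ibs) & ibs > thresholds$duplicate_ibs &
                   comp_n >= 20, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (drop[i] || drop[j]) next
      drop[if (cr_k[i] >= cr_k[j]) j else i] <- TRUE
    }
  }
  ids_k[!drop]
}

#' Admixture factors by principal-component extraction and varimax rotation
#'
#' Factor analysis of the per-sample admixture proportions: principal
#' components of the standardised proportions are extracted (a 3-component
#' simplex has rank 2, so at most 2 factors), the loadings are
#' varimax-rotated, and the rotation is applied to the standardised component
#' scores so the returned factors are exactly orthogonal with unit variance.
#'
#' @param proportions samples x 3 matrix, rows on the simplex.
#' @param n_factors requested number of factors (reduced to the rank with a
#'   warning if too large).
#' @return samples x n_factors matrix of standardised factor scores.
#' @export
admixture_factors <- function(proportions, n_factors = 2L) {
  proportions <- as.matrix(proportions)
  stopifnot(all(abs(rowSums(proportions) - 1) < 1e-6))
  sds <- apply(proportions, 2, stats::sd)
  Z <- scale(proportions)
  Z[, sds == 0] <- 0   # constant columns carry no admixture information
  sv <- svd(Z)
  rank <- sum(sv$d > max(sv$d) * 1e-8)
  if (n_factors > rank) {
    warning("n_factors reduced to rank ", rank)
    n_factors <- rank
  }
  d <- sv$d[seq_len(n_factors)]
  loadings <- sv$v[, seq_len(n_factors), drop = FALSE] %*%
    diag(d / sqrt(nrow(Z) - 1), n_factors)
  rot <- if (n_factors > 1) stats::varimax(loadings)$rotmat else
    matrix(1, 1, 1)
  # standardised PC scores are orthonormal; an orthogonal rotation keeps them so
  scores_std <- sv$u[, seq_len(n_factors), drop = FALSE] * sqrt(nrow(Z) - 1)
  scores <- scores_std %*% rot
  colnames(scores) <- paste0("factor", seq_len(n_factors))
  rownames(scores) <- rownames(proportions)
  scores
}

#' Greedy LD pruning
#'
#' Left-to-right scan in position order: a SNP is dropped when its squared
#' Pearson correlation (pairwise-complete) with any already-retained SNP in
#' the trailing window exceeds `r2_max`.
#'
#' @param genotypes samples x SNPs matrix (NA allowed).
#' @param r2_max r-squared threshold.
#' @param window number of retained SNPs looked back at.
#' @return character vector of retained SNP ids, in input order.
#' @export
ld_prune <- function(genotypes, r2_max = 0.2, window = 50L) {
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  kept <- integer(0)
  for (j in seq_len(ncol(genotypes))) {
    recent <- utils::tail(kept, window)
    ok <- TRUE
    for (i in rev(recent)) {
      r <- suppressWarnings(stats::cor(genotypes[, i], genotypes[, j],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r > r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  ids[kept]
}

#' Union test count across ancestries and its Bonferroni threshold
#'
#' @param kept_lists list of per-ancestry retained SNP id vectors.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @return list with `m` (union count) and `threshold` (alpha / m).
#' @export
union_test_count <- function(kept_lists, alpha = 0.05) {
  m <- length(unique(unlist(kept_lists)))
  list(m = m, threshold = if (m > 0) alpha / m else NA_real_)
}

#' Genomic-control inflation, scaled to 1,000 cases and 1,000 controls
#'
#' `lambda_GC` is the median 1-df chi-square statistic divided by the null
#' median 0.4549364; `lambda_1000 = 1 + (lambda_GC - 1) *
#' (1/n_cases + 1/n_controls) / (2/1000)`.
#'
#' @param chisq vector of 1-df chi-square statistics.
#' @param n_cases,n_controls study sizes.
#' @return list with lambda_gc, lambda_1000, n_cases, n_controls.
#' @export
genomic_control <- function(chisq, n_cases, n_controls) {
  chisq <- chisq[!is.na(chisq)]
  if (!length(chisq)) stop("no test statistics supplied")
  stopifnot(all(chisq >= 0), n_cases > 0, n_controls > 0)
  lambda_gc <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  lambda_1000 <- 1 + (lambda_gc - 1) *
    (1 / n_cases + 1 / n_controls) / (2 / 1000)
  list(lambda_gc = lambda_gc, lambda_1000 = lambda_1000,
       n_cases = n_cases, n_controls = n_controls)
}
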