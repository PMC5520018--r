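#' Cluster case risk-allele frequencies across ancestries
#'
#' K-means (k = 3, 25 restarts) on the per-SNP case RAF rows; the clusters
#' are then mapped to named categories by each cluster's mean contrast of the
#' AA frequency against the mean of the other ancestries: the most positive
#' cluster is `increased_AA`, the most negative `decreased_AA`, the middle
#' `comparable`.
#'
#' @param raf SNPs x ancestries matrix of case risk-allele frequencies; the
#'   AA-like column is named by `aa_col`.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param aa_col column name of the African-ancestry cohort.
#' @return data.frame snp_id/cluster/label; attribute `centers`.
#' @export
cluster_case_raf <- function(raf, k = 3L, seed = 1L, aa_col = "AA") {
  raf <- as.matrix(raf)
  if (anyNA(raf)) stop("missing RAFs; flag near-monomorphic SNPs upstream")
  if (k > nrow(raf)) stop("k exceeds the number of SNPs")
  set.seed(child_seed(seed, "profile"))
  km <- stats::kmeans(raf, centers = k, nstart = 25)
  stopifnot(aa_col %in% colnames(raf))
  other <- setdiff(colnames(raf), aa_col)
  contrast <- km$centers[, aa_col] - rowMeans(km$centers[, other,
                                                         drop = FALSE])
  labels <- rep("comparable", k)
  labels[which.max(contrast)] <- "increased_AA"
  labels[which.min(contrast)] <- "decreased_AA"
  ids <- rownames(raf)
  if (is.null(ids)) ids <- paste0("snp", seq_len(nrow(raf)))
  empty <- setdiff(seq_len(k), unique(km$cluster))
  out <- data.frame(snp_id = ids, cluster = km$cluster,
                    label = labels[km$cluster], stringsAsFactors = FALSE)
  attr(out, "centers") <- km$centers
  attr(out, "empty_clusters") <- empty
  out
}

#' Admixture deviation of risk alleles (cases only)
#'
#' For each SNP, the risk-allele average admixture is the allele-copy-weighted
#' mean of the per-sample admixture proportions (each case contributes with
#' weight equal to its risk-allele count); the deviation is that mean minus
#' the unweighted case average, reported for the CEU and YRI components (the
#' CHB deviation follows by simplex closure). Across SNPs, the CEU and YRI
#' deviations are compared by a paired two-sided Wilcoxon signed-rank test
#' (a paired t-test is reported alongside).
#'
#' @param genotypes cases x SNPs risk-allele count matrix (0/1/2, NA
#'   allowed).
#' @param admixture cases x 3 matrix with columns CEU/YRI/CHB.
#' @param risk_is_coded logical per SNP: TRUE if the coded allele is the risk
#'   allele (counts are flipped otherwise).
#' @return list with `deviations` (per SNP) and `paired_tests`.
#' @export
admixture_deviation <- function(genotypes, admixture,
                                risk_is_coded = rep(TRUE,
                                                    ncol(genotypes))) {
  genotypes <- as.matrix(genotypes)
  admixture <- as.matrix(admixture)
  stopifnot(nrow(genotypes) == nrow(admixture),
            all(c("CEU", "YRI") %in% colnames(admixture)))
  RA <- genotypes
  RA[, !risk_is_coded] <- 2 - RA[, !risk_is_coded]
  base <- colMeans(admixture)
  dev <- t(apply(RA, 2, function(w) {
    ok <- !is.na(w)
    if (sum(w[ok]) == 0) return(c(NA_real_, NA_real_, NA_real_))
    wm <- colSums(admixture[ok, , drop = FALSE] * w[ok]) / sum(w[ok])
    wm - base
  }))
  colnames(dev) <- colnames(admixture)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(genotypes)))
  deviations <- data.frame(snp_id = ids, dev,
                           monomorphic = is.na(dev[, 1]), row.names = NULL,
                           stringsAsFactors = FALSE)
  ok <- !deviations$monomorphic
  paired <- if (sum(ok) >= 2) {
    w <- stats::wilcox.test(deviations$CEU[ok], deviations$YRI[ok],
                            paired = TRUE, exact = FALSE)
    t <- stats::t.test(deviations$CEU[ok], deviations$YRI[ok], paired = TRUE)
    list(wilcoxon_p = w$p.value, t_p = t$p.value,
         mean_difference = mean(deviations$CEU[ok] - deviations$YRI[ok]))
  } else list(wilcoxon_p = NA_real_, t_p = NA_real_,
              mean_difference = NA_real_)
  list(deviations = deviations, paired_tests = paired)
}
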