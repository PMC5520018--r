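#' Reshape a long HLA dosage table to a samples x alleles matrix
#'
#' @param dosages data.frame with sample_id, locus, allele, dosage,
#'   best_guess.
#' @param value `"dosage"` or `"best_guess"`.
#' @return numeric matrix, rownames = sample ids, colnames = alleles;
#'   attribute `locus` maps alleles to loci.
#' @export
dosage_matrix <- function(dosages, value = c("dosage", "best_guess")) {
  value <- match.arg(value)
  samples <- unique(dosages$sample_id)
  alleles <- unique(dosages$allele)
  M <- matrix(0, length(samples), length(alleles),
              dimnames = list(samples, alleles))
  M[cbind(match(dosages$sample_id, samples),
          match(dosages$allele, alleles))] <- dosages[[value]]
  attr(M, "locus") <- dosages$locus[match(alleles, dosages$allele)]
  M
}

#' Alleles passing the minimum best-guess count filter
#'
#' An allele is analysed only if its best-guess allele count is at least
#' `min_count` in cases or in controls.
#'
#' @param dosages long dosage table.
#' @param phenotype named 0/1 vector (names = sample ids) or vector aligned
#'   to the unique sample order of `dosages`.
#' @param min_count minimum best-guess allele count.
#' @return data.frame allele/count_cases/count_controls/eligible.
#' @export
hla_allele_counts <- function(dosages, phenotype, min_count = 10L) {
  bg <- dosage_matrix(dosages, "best_guess")
  y <- align_phenotype(phenotype, rownames(bg))
  cc <- colSums(bg[y == 1, , drop = FALSE])
  cu <- colSums(bg[y == 0, , drop = FALSE])
  data.frame(allele = colnames(bg), count_cases = cc, count_controls = cu,
             eligible = cc >= min_count | cu >= min_count,
             row.names = NULL, stringsAsFactors = FALSE)
}

align_phenotype <- function(phenotype, ids) {
  if (!is.null(names(phenotype))) {
    y <- phenotype[ids]
    if (anyNA(y)) stop("phenotype missing for some samples")
    unname(y)
  } else {
    stopifnot(length(phenotype) == length(ids))
    phenotype
  }
}

#' Single HLA allele dosage association
#'
#' Logistic regression of status on the allele's expected dosage (additive
#' model accounting for imputation uncertainty), adjusted for admixture
#' covariates. Alleles below the best-guess count filter are skipped with a
#' recorded reason.
#'
#' @param dosage per-sample expected allele count in `[0, 2]`.
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @param allele label.
#' @param best_guess_cases,best_guess_controls best-guess allele counts used
#'   for the eligibility gate (NULL skips the gate).
#' @param min_count gate threshold.
#' @return one-row data.frame with beta/OR/CI/P or a skip reason.
#' @export
allele_association <- function(dosage, phenotype, covariates = NULL,
                               allele = "allele",
                               best_guess_cases = NULL,
                               best_guess_controls = NULL,
                               min_count = 10L) {
  skip <- function(reason) data.frame(
    allele = allele, beta = NA_real_, se = NA_real_, or_point = NA_real_,
    ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
    n_used = sum(!is.na(dosage)), note = reason, stringsAsFactors = FALSE)
  if (!is.null(best_guess_cases) &&
      best_guess_cases < min_count && best_guess_controls < min_count)
    return(skip(sprintf("min count %d", min_count)))
  ok <- !is.na(dosage) & !is.na(phenotype)
  d <- dosage[ok]; y <- phenotype[ok]
  if (stats::sd(d) == 0) return(skip("constant dosage"))
  X <- if (is.null(covariates)) cbind(dose = d) else
    cbind(dose = d, as.matrix(covariates)[ok, , drop = FALSE])
  f <- tryCatch(fit_logistic(y, X), error = function(e) NULL)
  if (is.null(f)) return(skip("fit failed"))
  beta <- unname(f$coef[2]); se <- unname(f$se[2])
  data.frame(allele = allele, beta = beta, se = se, or_point = exp(beta),
             ci_lo = exp(beta - 1.959964 * se),
             ci_hi = exp(beta + 1.959964 * se),
             p = wald_p(beta, se), n_used = length(d), note = "",
             stringsAsFactors = FALSE)
}

#' Stepwise multi-locus HLA modelling
#'
#' Forward selection with backward elimination over all eligible allele
#' dosages across loci (entry and exit at `p_enter`/`p_exit`, default 0.01).
#' The per-locus sum-to-2 constraint makes one allele per locus redundant, so
#' the most frequent allele of each locus is dropped as the reference before
#' selection.
#'
#' @param dosages long dosage table.
#' @param phenotype 0/1 vector (named by sample id, or aligned).
#' @param covariates adjustment matrix aligned to the dosage-table samples.
#' @param min_count best-guess eligibility gate.
#' @param p_enter,p_exit entry/exit criteria.
#' @return list with `selected` alleles, `conditional` estimates and the
#'   `reference_alleles` dropped per locus.
#' @export
hla_stepwise <- function(dosages, phenotype, covariates = NULL,
                         min_count = 10L, p_enter = 0.01, p_exit = 0.01) {
  M <- dosage_matrix(dosages, "dosage")
  y <- align_phenotype(phenotype, rownames(M))
  counts <- hla_allele_counts(dosages, y, min_count)
  loci <- attr(M, "locus")
  ref <- tapply(seq_len(ncol(M)), loci, function(ix)
    colnames(M)[ix][which.max(colSums(M[, ix, drop = FALSE]))])
  elig <- counts$allele[counts$eligible]
  elig <- setdiff(elig, unlist(ref))
  if (!length(elig))
    return(list(selected = character(0),
                conditional = data.frame(snp_id = character(),
                                         beta = numeric(), se = numeric(),
                                         p = numeric()),
                reference_alleles = unlist(ref)))
  res <- regional_stepwise(M[, elig, drop = FALSE], y, covariates,
                           p_enter = p_enter, p_exit = p_exit)
  names(res$conditional)[names(res$conditional) == "snp_id"] <- "allele"
  list(selected = res$selected, conditional = res$conditional,
       reference_alleles = unlist(ref),
       skipped_collinear = res$skipped_collinear)
}

#' SNP association conditional on the stepwise-selected HLA alleles
#'
#' Applies the standard single-SNP model-selection rule with the selected
#' HLA allele dosages appended to the covariates.
#'
#' @param genotype SNP 0/1/2 vector.
#' @param hla_dosages samples x selected-alleles matrix (may have 0 columns).
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @param ... passed to [test_snp()].
#' @return an assoc-result row.
#' @export
snp_given_hla <- function(genotype, hla_dosages, phenotype,
                          covariates = NULL, ...) {
  hla_dosages <- as.matrix(hla_dosages)
  Z <- if (ncol(hla_dosages) == 0) covariates
  else if (is.null(covariates)) hla_dosages
  else cbind(as.matrix(covariates), hla_dosages)
  test_snp(genotype, phenotype, Z, ...)
}

#' Compound risk-allele heterozygosity analysis
#'
#' Samples are classified into six genotype classes from rounded best-guess
#' dosages of the two tagging alleles (DR3-like and DR15-like): 0/0, either
#' heterozygote, either homozygote, and the compound heterozygote. Reports
#' (i) genotypic ORs vs the 0/0 baseline, (ii) Wald contrasts of the
#' compound-heterozygote class against each homozygote class, (iii) the
#' carrier-product interaction P, and (iv) per-allele dominance lack-of-fit
#' (1-df LRT, genotypic indicators vs linear allele dose).
#'
#' @param dr3,dr15 per-sample dosages of the two tagging alleles.
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @return list with `classes`, `genotypic` (ORs vs baseline),
#'   `het_vs_hom` (Wald contrasts), `interaction_p`, `dominance_lof`.
#' @export
compound_het <- function(dr3, dr15, phenotype, covariates = NULL) {
  n3 <- pmin(pmax(round(dr3), 0), 2)
  n15 <- pmin(pmax(round(dr15), 0), 2)
  over <- n3 + n15 > 2   # rounding can momentarily exceed two haplotypes
  n15[over] <- 2 - n3[over]
  cls <- rep("0/0", length(n3))
  cls[n3 == 1 & n15 == 0] <- "dr3_het"
  cls[n3 == 0 & n15 == 1] <- "dr15_het"
  cls[n3 == 2] <- "dr3_hom"
  cls[n15 == 2] <- "dr15_hom"
  cls[n3 == 1 & n15 == 1] <- "compound_het"
  lv <- c("0/0", "dr3_het", "dr15_het", "dr3_hom", "dr15_hom", "compound_het")
  cls <- factor(cls, levels = lv)
  present <- levels(cls)[table(cls) > 0]
  ok <- !is.na(phenotype)
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)

  out <- list(classes = table(cls))
  nonbase <- setdiff(present, "0/0")
  if (!("0/0" %in% present) || !length(nonbase) ||
      length(unique(phenotype[ok])) < 2) {
    out$genotypic <- data.frame(class = character(), or = numeric(),
                                ci_lo = numeric(), ci_hi = numeric(),
                                p = numeric())
    out$het_vs_hom <- data.frame(contrast = character(), beta = numeric(),
                                 se = numeric(), p = numeric(),
                                 note = character())
    out$interaction_p <- NA_real_
    out$dominance_lof <- c(dr3 = NA_real_, dr15 = NA_real_)
    out$note <- "insufficient genotype classes"
    return(out)
  }
  ind <- sapply(nonbase, function(l) as.numeric(cls == l))
  colnames(ind) <- nonbase
  X <- if (is.null(Z)) ind else cbind(ind, Z)
  f <- fit_logistic(phenotype[ok], X[ok, , drop = FALSE])
  idx <- stats::setNames(seq_along(nonbase) + 1L, nonbase)
  b <- f$coef[idx]; se <- f$se[idx]
  out$genotypic <- data.frame(
    class = nonbase, beta = unname(b), se = unname(se),
    or = exp(unname(b)),
    ci_lo = exp(unname(b) - 1.959964 * unname(se)),
    ci_hi = exp(unname(b) + 1.959964 * unname(se)),
    p = wald_p(unname(b), unname(se)), stringsAsFactors = FALSE)

  contrast <- function(hom) {
    if (!("compound_het" %in% nonbase) || !(hom %in% nonbase))
      return(data.frame(contrast = paste0("compound_het vs ", hom),
                        beta = NA_real_, se = NA_real_, p = NA_real_,
                        note = "class absent", stringsAsFactors = FALSE))
    i <- idx[["compound_het"]]; j <- idx[[hom]]
    d <- f$coef[i] - f$coef[j]
    v <- f$vcov[i, i] + f$vcov[j, j] - 2 * f$vcov[i, j]
    data.frame(contrast = paste0("compound_het vs ", hom), beta = unname(d),
               se = sqrt(v), p = wald_p(unname(d), sqrt(v)), note = "",
               stringsAsFactors = FALSE)
  }
  out$het_vs_hom <- rbind(contrast("dr3_hom"), contrast("dr15_hom"))

  # carrier-indicator product interaction
  c3 <- as.numeric(n3 > 0); c15 <- as.numeric(n15 > 0)
  if (stats::sd(c3) > 0 && stats::sd(c15) > 0 &&
      stats::sd(c3 * c15) > 0) {
    Xi <- cbind(c3 = c3, c15 = c15, prod = c3 * c15)
    if (!is.null(Z)) Xi <- cbind(Xi, Z)
    fi <- tryCatch(fit_logistic(phenotype[ok], Xi[ok, , drop = FALSE]),
                   error = function(e) NULL)
    out$interaction_p <- if (is.null(fi) || fi$aliased[4]) NA_real_ else
      wald_p(fi$coef["prod"], fi$se["prod"])
  } else out$interaction_p <- NA_real_

  # per-allele dominance lack-of-fit: genotypic indicators vs linear dose
  lof <- function(nall) {
    if (length(unique(nall)) < 3) return(NA_real_)
    X1 <- cbind(het = as.numeric(nall == 1), hom = as.numeric(nall == 2))
    X0 <- cbind(dose = nall)
    if (!is.null(Z)) { X1 <- cbind(X1, Z); X0 <- cbind(X0, Z) }
    f1 <- tryCatch(fit_logistic(phenotype[ok], X1[ok, , drop = FALSE]),
                   error = function(e) NULL)
    f0 <- tryCatch(fit_logistic(phenotype[ok], X0[ok, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(f1) || is.null(f0)) return(NA_real_)
    stats::pchisq(max(2 * (f1$loglik - f0$loglik), 0), 1, lower.tail = FALSE)
  }
  out$dominance_lof <- c(dr3 = lof(n3), dr15 = lof(n15))
  out
}

#' HLA-by-SNP and HLA-by-sex Wald interaction tests
#'
#' Per pair, the logistic model holds covariates, both main effects and
#' their centred cross-product; the product term is tested by a 1-df Wald
#' test. A BH-FDR column adjusts over all tested pairs.
#'
#' @param allele_dosages samples x alleles matrix.
#' @param partners samples x SNPs matrix, or a sex vector ("F"/"M" or 0/1).
#' @param phenotype 0/1 vector.
#' @param covariates adjustment matrix or NULL.
#' @return data.frame allele/partner/beta/se/p/fdr_adjusted_p/note.
#' @export
hla_interaction_tests <- function(allele_dosages, partners, phenotype,
                                  covariates = NULL) {
  allele_dosages <- as.matrix(allele_dosages)
  if (is.null(dim(partners))) {
    pname <- "sex"
    partners <- matrix(if (is.numeric(partners)) partners else
      as.numeric(partners == "F"), ncol = 1,
      dimnames = list(NULL, pname))
  }
  partners <- as.matrix(partners)
  Z <- if (is.null(covariates)) NULL else as.matrix(covariates)
  rows <- list()
  for (a in colnames(allele_dosages)) for (b in colnames(partners)) {
    da <- allele_dosages[, a]; db <- partners[, b]
    ok <- !is.na(da) & !is.na(db) & !is.na(phenotype)
    cp <- (da - mean(da[ok])) * (db - mean(db[ok]))
    X <- cbind(a = da, b = db, cp = cp)
    if (!is.null(Z)) X <- cbind(X, Z)
    f <- tryCatch(fit_logistic(phenotype[ok], X[ok, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(f) || f$aliased[4] || !is.finite(f$se[["cp"]])) {
      rows[[paste(a, b)]] <- data.frame(allele = a, partner = b,
                                        beta = NA_real_, se = NA_real_,
                                        p = NA_real_,
                                        note = "product inestimable",
                                        stringsAsFactors = FALSE)
    } else {
      rows[[paste(a, b)]] <- data.frame(
        allele = a, partner = b, beta = unname(f$coef[["cp"]]),
        se = unname(f$se[["cp"]]),
        p = wald_p(f$coef[["cp"]], f$se[["cp"]]), note = "",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr_adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Pairwise p-distance over an amino-acid alignment
#'
#' Fraction of differing columns among pairwise non-gap positions.
#'
#' @param sequences named character vector of equal-length aligned sequences.
#' @return symmetric distance matrix.
#' @export
p_distance <- function(sequences) {
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) stop("sequences are not aligned")
  M <- do.call(rbind, strsplit(sequences, ""))
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  gap <- M == "-" | M == "."
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- !gap[i, ] & !gap[j, ]
    D[i, j] <- D[j, i] <-
      if (any(use)) mean(M[i, use] != M[j, use]) else NA_real_
  }
  D
}

#' Neighbour-joining cluster tree of HLA allele protein sequences
#'
#' Builds the unrooted NJ tree on amino-acid p-distances and attaches the
#' association overlay: per-cohort odds ratios shown only for alleles with
#' association P < `p_show` (the display rule), and stepwise-model membership
#' flags.
#'
#' @param sequences named character vector of aligned protein sequences
#'   (>= 3 for a tree; with 2 the distance matrix is returned without one).
#' @param association data.frame with columns allele, cohort, or_point, p
#'   (optional).
#' @param stepwise_alleles character vector of stepwise-selected alleles.
#' @param p_show overlay display threshold.
#' @return list with `tree` (phylo or NULL), `newick`, `distances`,
#'   `annotations`.
#' @export
build_nj_tree <- function(sequences, association = NULL,
                          stepwise_alleles = character(0), p_show = 0.01) {
  D <- p_distance(sequences)
  if (nrow(D) < 3) {
    return(list(tree = NULL, newick = NA_character_, distances = D,
                annotations = NULL, note = "fewer than 3 sequences"))
  }
  tree <- ape::nj(as.dist(D))
  ann <- data.frame(allele = names(sequences),
                    stepwise = names(sequences) %in% stepwise_alleles,
                    stringsAsFactors = FALSE)
  if (!is.null(association)) {
    shown <- association[!is.na(association$p) & association$p < p_show, ,
                         drop = FALSE]
    ann$or_overlay <- vapply(ann$allele, function(al) {
      rows <- shown[shown$allele == al, , drop = FALSE]
      if (!nrow(rows)) return(NA_character_)
      paste(sprintf("%s:%.2f", rows$cohort, rows$or_point), collapse = ",")
    }, character(1))
  }
  list(tree = tree, newick = ape::write.tree(tree), distances = D,
       annotations = ann)
}

#' Residues unique to a set of risk alleles
#'
#' The comparison set is either given explicitly or formed from the non-risk
#' alleles with sequence identity at least `identity_min` to any risk allele.
#' Returned are the alignment positions where all risk alleles share one
#' residue that no comparison allele carries, numbered on the mature protein:
#' columns past the signal peptide count from +1, columns inside it count
#' back from -1.
#'
#' @param sequences named aligned protein sequences.
#' @param risk_alleles names of the risk alleles.
#' @param comparison_alleles explicit comparison set (overrides the identity
#'   rule).
#' @param identity_min identity threshold for the automatic comparison set.
#' @param signal_peptide_length residues of signal peptide preceding the
#'   mature protein (0 = alignment numbering).
#' @return data.frame position (mature numbering), column (alignment),
#'   residue; attribute `comparison_set`.
#' @export
risk_unique_residues <- function(sequences, risk_alleles,
                                 comparison_alleles = NULL,
                                 identity_min = 0.95,
                                 signal_peptide_length = 0L) {
  stopifnot(length(risk_alleles) > 0,
            all(risk_alleles %in% names(sequences)))
  M <- do.call(rbind, strsplit(sequences, ""))
  rownames(M) <- names(sequences)
  if (is.null(comparison_alleles)) {
    others <- setdiff(names(sequences), risk_alleles)
    D <- p_distance(sequences)
    comparison_alleles <- others[vapply(others, function(o)
      any(1 - D[o, risk_alleles] >= identity_min), logical(1))]
  }
  empty <- data.frame(position = integer(), column = integer(),
                      residue = character(), stringsAsFactors = FALSE)
  if (!length(comparison_alleles)) {
    attr(empty, "comparison_set") <- character(0)
    attr(empty, "note") <- "empty comparison set"
    return(empty)
  }
  risk <- M[risk_alleles, , drop = FALSE]
  comp <- M[comparison_alleles, , drop = FALSE]
  hits <- list()
  for (col in seq_len(ncol(M))) {
    rr <- unique(risk[, col])
    if (length(rr) != 1 || rr %in% c("-", ".")) next
    if (rr %in% comp[, col]) next
    pos <- if (col > signal_peptide_length) col - signal_peptide_length
    else col - signal_peptide_length - 1L
    hits[[length(hits) + 1L]] <- data.frame(position = pos, column = col,
                                            residue = rr,
                                            stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, hits) else empty
  attr(out, "comparison_set") <- comparison_alleles
  out
}
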