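#' Derive a per-stage child seed from a global seed
#'
#' Stages of the pipeline draw their random numbers under independent child
#' seeds so that each stage is reproducible in isolation. The expansion is a
#' small counter-based mix kept inside the 32-bit signed range.
#'
#' @param seed integer global seed.
#' @param stage integer stage counter (>= 0) or a known stage name.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stages <- c(cohort = 1L, hla = 2L, annotations = 3L, proteins = 4L,
                split = 5L, qc = 6L, assoc = 7L, load = 8L, profile = 9L)
    if (!stage %in% names(stages)) stop("unknown stage name: ", stage)
    stage <- stages[[stage]]
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stage * 16807) %% 2147483647)
}

#' Simulation configuration for a multi-ancestry case-control cohort
#'
#' Defines the generating model for three admixed ancestral cohorts
#' (European-, African- and Amerindian-like, anchored on CEU/YRI/CHB-style
#' components). Disease status follows a logistic model with additive SNP
#' effects, an optional supra-additive term in the centred risk-allele count,
#' and HLA genotype-class effects that allow dominance and a
#' compound-heterozygote excess.
#'
#' @param n_cases,n_controls named integer vectors (one entry per ancestry).
#' @param n_snps number of SNPs on the panel.
#' @param raf n_snps x n_ancestry matrix of risk-allele frequencies in (0,1);
#'   if NULL, drawn uniformly in `raf_range` with ancestry-specific jitter.
#' @param raf_range range used when `raf` is NULL.
#' @param beta per-SNP additive log-odds per risk allele (>= 0); default all 0.
#' @param theta supra-additive coefficient: log-odds per squared centred
#'   risk-allele count over the causal SNPs (0 = purely additive).
#' @param b0 baseline logit (controls the population prevalence before
#'   case-control ascertainment).
#' @param missing_rate per-genotype missingness probability.
#' @param hla_haplotype_freqs n_ancestry x 3 matrix of haplotype frequencies
#'   (columns DR3-like, DR15-like, neutral); rows may sum to <= 1, the
#'   remainder is neutral.
#' @param hla_genotype_logits named length-6 vector of log-odds added for the
#'   HLA genotype classes `c("0/0","dr3_het","dr15_het","dr3_hom","dr15_hom",
#'   "compound_het")`; the baseline class must be 0.
#' @param dosage_noise_sd sd of the truncated Gaussian imputation noise put on
#'   HLA allele dosages.
#' @param admixture_concentration n_ancestry x 3 matrix of Dirichlet
#'   concentration parameters for the CEU/YRI/CHB-like components.
#' @param age_load_slope years of diagnosis age per unit weighted load
#'   (negative = higher load, earlier onset).
#' @param age_base,age_sd mean and residual sd of diagnosis age at zero load.
#' @param sex_female_prob length-2 vector: P(female) in cases and in controls.
#' @param oversample_limit maximum oversampling factor for the retrospective
#'   (case-control) ascertainment before giving up.
#' @param seed integer default seed used when callers do not pass one.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_cases = c(EA = 2000, AA = 1000, HA = 1000),
                       n_controls = c(EA = 2000, AA = 1000, HA = 1000),
                       n_snps = 500,
                       raf = NULL,
                       raf_range = c(0.05, 0.5),
                       beta = NULL,
                       theta = 0,
                       b0 = -1,
                       missing_rate = 0.002,
                       hla_haplotype_freqs = NULL,
                       hla_genotype_logits = NULL,
                       dosage_noise_sd = 0.05,
                       admixture_concentration = NULL,
                       age_load_slope = 0,
                       age_base = 35,
                       age_sd = 10,
                       sex_female_prob = c(case = 0.9, control = 0.6),
                       oversample_limit = 100,
                       seed = 1L) {
  ancestries <- names(n_cases)
  if (is.null(ancestries)) ancestries <- paste0("POP", seq_along(n_cases))
  stopifnot(length(n_controls) == length(n_cases),
            all(n_cases > 0), all(n_controls > 0),
            n_snps >= 1, is.finite(theta), missing_rate >= 0, missing_rate <= 1,
            dosage_noise_sd >= 0)
  k <- length(ancestries)
  if (is.null(beta)) beta <- rep(0, n_snps)
  stopifnot(length(beta) == n_snps, all(beta >= 0))
  if (!is.null(raf)) {
    raf <- as.matrix(raf)
    stopifnot(nrow(raf) == n_snps, ncol(raf) == k,
              all(raf > 0), all(raf < 1))
  }
  if (is.null(hla_haplotype_freqs)) {
    hla_haplotype_freqs <- matrix(rep(c(0.12, 0.10), each = k), nrow = k,
                                  dimnames = list(ancestries, NULL))
    hla_haplotype_freqs <- cbind(hla_haplotype_freqs,
                                 1 - rowSums(hla_haplotype_freqs))
  }
  hla_haplotype_freqs <- as.matrix(hla_haplotype_freqs)
  if (ncol(hla_haplotype_freqs) == 2)
    hla_haplotype_freqs <- cbind(hla_haplotype_freqs,
                                 1 - rowSums(hla_haplotype_freqs))
  colnames(hla_haplotype_freqs) <- c("dr3", "dr15", "neutral")
  stopifnot(nrow(hla_haplotype_freqs) == k,
            all(hla_haplotype_freqs >= 0),
            all(abs(rowSums(hla_haplotype_freqs) - 1) < 1e-8))
  # dominance-consistent defaults: homozygotes barely exceed heterozygotes,
  # while the compound heterozygote carries a clear excess
  if (is.null(hla_genotype_logits))
    hla_genotype_logits <- c(`0/0` = 0, dr3_het = 0.7, dr15_het = 0.6,
                             dr3_hom = 0.8, dr15_hom = 0.7,
                             compound_het = 1.5)
  stopifnot(length(hla_genotype_logits) == 6,
            hla_genotype_logits[[1]] == 0,
            all(is.finite(hla_genotype_logits)))
  names(hla_genotype_logits) <- c("0/0", "dr3_het", "dr15_het",
                                  "dr3_hom", "dr15_hom", "compound_het")
  if (is.null(admixture_concentration)) {
    admixture_concentration <- matrix(2, k, 3)
    # anchor each cohort on its dominant reference component
    for (i in seq_len(k)) admixture_concentration[i, min(i, 3)] <- 30
  }
  admixture_concentration <- as.matrix(admixture_concentration)
  stopifnot(nrow(admixture_concentration) == k,
            ncol(admixture_concentration) == 3,
            all(admixture_concentration > 0))
  structure(list(
    ancestries = ancestries, n_cases = n_cases, n_controls = n_controls,
    n_snps = n_snps, raf = raf, raf_range = raf_range, beta = beta,
    theta = theta, b0 = b0, missing_rate = missing_rate,
    hla_haplotype_freqs = hla_haplotype_freqs,
    hla_genotype_logits = hla_genotype_logits,
    dosage_noise_sd = dosage_noise_sd,
    admixture_concentration = admixture_concentration,
    age_load_slope = age_load_slope, age_base = age_base, age_sd = age_sd,
    sex_female_prob = sex_female_prob, oversample_limit = oversample_limit,
    seed = as.integer(seed)), class = "sim_config")
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

hla_class <- function(h1, h2) {
  # haplotypes coded 1 = DR3-like, 2 = DR15-like, 3 = neutral
  n3 <- (h1 == 1) + (h2 == 1)
  n15 <- (h1 == 2) + (h2 == 2)
  cls <- rep("0/0", length(h1))
  cls[n3 == 1 & n15 == 0] <- "dr3_het"
  cls[n3 == 0 & n15 == 1] <- "dr15_het"
  cls[n3 == 2] <- "dr3_hom"
  cls[n15 == 2] <- "dr15_hom"
  cls[n3 == 1 & n15 == 1] <- "compound_het"
  cls
}

#' Simulate a multi-ancestry case-control cohort
#'
#' Genotypes are drawn in Hardy-Weinberg proportions within each ancestry from
#' the configured risk-allele frequencies; disease status is assigned under
#' `logit P(case) = b0 + sum_k beta_k g_k + theta (L - E[L])^2 + HLA class
#' logit`, with `L` the risk-allele count over causal SNPs; cases and controls
#' are then ascertained retrospectively by oversampling the population until
#' the configured quotas are met.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed (defaults to the config seed).
#' @return a list with `genotypes` (samples x SNPs integer matrix, NA =
#'   missing), `samples` (data.frame of metadata incl. admixture proportions
#'   and HLA haplotypes) and `snps` (data.frame of panel annotation).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(seed, "cohort"))
  k <- length(config$ancestries)
  m <- config$n_snps
  raf <- config$raf
  if (is.null(raf)) {
    base <- stats::runif(m, config$raf_range[1], config$raf_range[2])
    raf <- sapply(seq_len(k), function(i) {
      p <- base + stats::rnorm(m, 0, 0.08)
      pmin(pmax(p, 0.02), 0.98)
    })
  }
  causal <- which(config$beta > 0)
  eL <- function(anc) sum(2 * raf[causal, anc])

  geno <- list(); meta <- list()
  for (a in seq_len(k)) {
    need_case <- config$n_cases[a]; need_ctrl <- config$n_controls[a]
    got_case <- 0L; got_ctrl <- 0L
    gc_list <- list(); mc_list <- list(); rounds <- 0L
    batch <- max(2000L, 2L * (need_case + need_ctrl))
    drawn <- 0L
    while ((got_case < need_case || got_ctrl < need_ctrl)) {
      rounds <- rounds + 1L
      if (drawn > config$oversample_limit * (need_case + need_ctrl)) {
        short <- if (got_case < need_case) "cases" else "controls"
        stop(sprintf(
          "retrospective sampling failed: only %d/%d %s after %dx oversampling; adjust b0 or effect sizes",
          if (short == "cases") got_case else got_ctrl,
          if (short == "cases") need_case else need_ctrl,
          short, config$oversample_limit))
      }
      n <- batch; drawn <- drawn + n
      g <- matrix(stats::rbinom(n * m, 2L, rep(raf[, a], each = n)), nrow = n)
      h1 <- sample.int(3L, n, replace = TRUE,
                       prob = config$hla_haplotype_freqs[a, ])
      h2 <- sample.int(3L, n, replace = TRUE,
                       prob = config$hla_haplotype_freqs[a, ])
      cls <- hla_class(h1, h2)
      lin <- config$b0 + as.vector(g %*% config$beta) +
        config$hla_genotype_logits[cls]
      if (length(causal) && config$theta != 0) {
        L <- rowSums(g[, causal, drop = FALSE])
        lin <- lin + config$theta * (L - eL(a))^2
      }
      status <- stats::rbinom(n, 1L, stats::plogis(lin))
      keep_case <- which(status == 1L)[seq_len(min(sum(status == 1L),
                                                   need_case - got_case))]
      keep_ctrl <- which(status == 0L)[seq_len(min(sum(status == 0L),
                                                   need_ctrl - got_ctrl))]
      keep <- c(keep_case, keep_ctrl)
      if (length(keep)) {
        gc_list[[rounds]] <- g[keep, , drop = FALSE]
        mc_list[[rounds]] <- data.frame(status = status[keep],
                                        h1 = h1[keep], h2 = h2[keep])
        got_case <- got_case + length(keep_case)
        got_ctrl <- got_ctrl + length(keep_ctrl)
      }
    }
    g <- do.call(rbind, gc_list)
    md <- do.call(rbind, mc_list)
    md$ancestry <- config$ancestries[a]
    # order cases first for readability; ids assigned after pooling
    o <- order(-md$status)
    geno[[a]] <- g[o, , drop = FALSE]
    meta[[a]] <- md[o, , drop = FALSE]
  }
  g <- do.call(rbind, geno)
  md <- do.call(rbind, meta)
  n_tot <- nrow(g)
  md$sample_id <- sprintf("S%05d", seq_len(n_tot))

  admix <- matrix(NA_real_, n_tot, 3,
                  dimnames = list(NULL, c("CEU", "YRI", "CHB")))
  for (a in seq_len(k)) {
    idx <- which(md$ancestry == config$ancestries[a])
    admix[idx, ] <- rdirichlet1(length(idx),
                                config$admixture_concentration[a, ])
  }
  md$admix_CEU <- admix[, 1]; md$admix_YRI <- admix[, 2]
  md$admix_CHB <- admix[, 3]
  md$sex <- ifelse(stats::runif(n_tot) <
                     ifelse(md$status == 1, config$sex_female_prob[1],
                            config$sex_female_prob[2]), "F", "M")
  wload <- as.vector(g %*% config$beta)
  md$age_dx <- NA_real_
  cases <- md$status == 1
  md$age_dx[cases] <- config$age_base +
    config$age_load_slope * wload[cases] +
    stats::rnorm(sum(cases), 0, config$age_sd)
  md$hla_class <- hla_class(md$h1, md$h2)

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(g)) < config$missing_rate
    g[miss] <- NA_integer_
  }
  snp_ids <- sprintf("snp%05d", seq_len(m))
  rownames(g) <- md$sample_id; colnames(g) <- snp_ids
  # panel positions: spread over 10 chromosome-like blocks, 25 kb spacing
  chr <- rep(seq_len(10), length.out = m)
  pos <- integer(m)
  for (cc in unique(chr)) pos[chr == cc] <- seq_len(sum(chr == cc)) * 25000L
  snps <- data.frame(snp_id = snp_ids, chr = chr, pos = pos,
                     allele_risk = "A", allele_other = "G",
                     beta_true = config$beta, stringsAsFactors = FALSE)
  for (a in seq_len(k)) snps[[paste0("raf_", config$ancestries[a])]] <- raf[, a]
  rownames(md) <- NULL
  list(genotypes = g,
       samples = md[, c("sample_id", "ancestry", "status", "sex", "age_dx",
                        "admix_CEU", "admix_YRI", "admix_CHB",
                        "h1", "h2", "hla_class")],
       snps = snps)
}

#' Simulate HLA allele dosages from the cohort's haplotype assignments
#'
#' True allele counts at DRB1 come from the cohort's simulated haplotypes
#' (DR3-like = DRB1*03:01, DR15-like = DRB1*15:01, neutral haplotypes spread
#' over a set of neutral DRB1 alleles); additional loci are filled with
#' independent neutral alleles. Counts are perturbed with truncated Gaussian
#' imputation noise and renormalised so each sample's dosages at a locus sum
#' to exactly 2; best-guess counts are the rounded noisy dosages.
#'
#' @param config a [sim_config()].
#' @param samples the `samples` data.frame from [simulate_cohort()].
#' @param seed integer seed.
#' @param loci character vector of loci to simulate (DRB1 always included).
#' @return data.frame with columns sample_id, locus, allele, dosage,
#'   best_guess; attribute `alleles` lists the allele panel per locus.
#' @export
simulate_hla <- function(config, samples, seed = config$seed,
                         loci = c("DRB1", "DQB1", "A")) {
  stopifnot(inherits(config, "sim_config"), config$dosage_noise_sd >= 0)
  set.seed(child_seed(seed, "hla"))
  loci <- union("DRB1", loci)
  n <- nrow(samples)
  out <- list()
  allele_panel <- list()
  neutral_drb1 <- c("DRB1*01:01", "DRB1*04:01", "DRB1*07:01", "DRB1*11:01")
  for (locus in loci) {
    if (locus == "DRB1") {
      alleles <- c("DRB1*03:01", "DRB1*15:01", neutral_drb1)
      counts <- matrix(0L, n, length(alleles),
                       dimnames = list(samples$sample_id, alleles))
      for (hcol in c("h1", "h2")) {
        h <- samples[[hcol]]
        counts[cbind(which(h == 1), 1L)] <-
          counts[cbind(which(h == 1), 1L)] + 1L
        counts[cbind(which(h == 2), 2L)] <-
          counts[cbind(which(h == 2), 2L)] + 1L
        neu <- which(h == 3)
        pick <- 2L + sample.int(length(neutral_drb1), length(neu),
                                replace = TRUE)
        counts[cbind(neu, pick)] <- counts[cbind(neu, pick)] + 1L
      }
    } else {
      alleles <- paste0(locus, "*", sprintf("%02d:01", 1:5))
      counts <- matrix(0L, n, length(alleles),
                       dimnames = list(samples$sample_id, alleles))
      freqs <- c(0.35, 0.25, 0.2, 0.12, 0.08)
      for (j in 1:2) {
        pick <- sample.int(length(alleles), n, replace = TRUE, prob = freqs)
        counts[cbind(seq_len(n), pick)] <- counts[cbind(seq_len(n), pick)] + 1L
      }
    }
    dos <- counts
    if (config$dosage_noise_sd > 0) {
      noise <- stats::rnorm(length(dos), 0, config$dosage_noise_sd)
      dos <- pmin(pmax(counts + noise, 0), 2)
      dos <- dos / rowSums(dos) * 2  # per-locus dosages must sum to 2
    }
    out[[locus]] <- data.frame(
      sample_id = rep(samples$sample_id, times = ncol(dos)),
      locus = locus,
      allele = rep(colnames(dos), each = n),
      dosage = as.vector(dos),
      best_guess = as.integer(round(as.vector(dos))),
      stringsAsFactors = FALSE)
    allele_panel[[locus]] <- alleles
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alleles") <- allele_panel
  res
}

#' Simulate per-SNP functional annotations, flanking bases and eQTL records
#'
#' @param snps SNP table from [simulate_cohort()].
#' @param seed integer seed.
#' @param flag_rates named rates for the Boolean/leveled annotation flags.
#' @param eqtl_rate expected number of eQTL records per SNP.
#' @return list of data.frames `flanks` (snp_id, left_base, right_base),
#'   `annotations` (one row per SNP, rubric fields) and `eqtl`
#'   (snp_id, gene, tissue, p).
#' @export
simulate_annotations <- function(snps, seed = 1L,
                                 flag_rates = c(eqtl = 0.15,
                                                nonsense_or_missense = 0.03,
                                                conserved = 0.2,
                                                dnase_5 = 0.25,
                                                bound_protein = 0.3),
                                 eqtl_rate = 0.3) {
  set.seed(child_seed(seed, "annotations"))
  m <- nrow(snps)
  bases <- c("A", "C", "G", "T")
  flanks <- data.frame(snp_id = snps$snp_id,
                       left_base = sample(bases, m, replace = TRUE),
                       right_base = sample(bases, m, replace = TRUE),
                       stringsAsFactors = FALSE)
  lv <- function(levels, probs) sample(levels, m, replace = TRUE, prob = probs)
  ann <- data.frame(
    snp_id = snps$snp_id,
    eqtl = stats::runif(m) < flag_rates[["eqtl"]],
    nonsense_or_missense = stats::runif(m) <
      flag_rates[["nonsense_or_missense"]],
    blcl_promoter = lv(c("none", "weak", "active"), c(0.7, 0.2, 0.1)),
    blcl_enhancer = lv(c("none", "weak"), c(0.8, 0.2)),
    tss_15 = lv(c("none", "weak", "upstream_flanking", "active_or_poised"),
                c(0.6, 0.2, 0.1, 0.1)),
    enhancer_15 = lv(c("none", "any"), c(0.7, 0.3)),
    conserved = stats::runif(m) < flag_rates[["conserved"]],
    dnase_5 = stats::runif(m) < flag_rates[["dnase_5"]],
    bound_protein = stats::runif(m) < flag_rates[["bound_protein"]],
    stringsAsFactors = FALSE)
  n_eqtl <- stats::rpois(m, eqtl_rate)
  idx <- rep(seq_len(m), n_eqtl)
  eqtl <- data.frame(
    snp_id = snps$snp_id[idx],
    gene = paste0("GENE", sample.int(200, length(idx), replace = TRUE)),
    tissue = sample(c("whole_blood", "spleen", "LCL"), length(idx),
                    replace = TRUE),
    p = 10^(-stats::runif(length(idx), 2, 40)),
    stringsAsFactors = FALSE)
  list(flanks = flanks, annotations = ann, eqtl = eqtl)
}

#' Simulate an aligned set of HLA protein sequences with planted risk residues
#'
#' A random reference sequence is mutated per allele; alleles named in
#' `risk_alleles` carry the planted residues at the given alignment columns,
#' all other alleles carry an alternative residue there.
#'
#' @param n_alleles number of alleles (>= 3 for tree building).
#' @param length alignment length in residues.
#' @param risk_positions data.frame with columns `position` (alignment column)
#'   and `residue` (single-letter amino acid) planted in risk alleles.
#' @param risk_alleles character names of the risk alleles; defaults to the
#'   first allele.
#' @param allele_names optional character vector of allele names (unique).
#' @param mutation_rate per-column substitution probability off the reference.
#' @param seed integer seed.
#' @return named character vector of aligned sequences.
#' @export
simulate_hla_proteins <- function(n_alleles, length,
                                  risk_positions = data.frame(
                                    position = integer(), residue = character()),
                                  risk_alleles = NULL,
                                  allele_names = NULL,
                                  mutation_rate = 0.05,
                                  seed = 1L) {
  set.seed(child_seed(seed, "proteins"))
  stopifnot(n_alleles >= 2, length >= 1,
            all(risk_positions$position <= length),
            all(risk_positions$position >= 1))
  if (is.null(allele_names))
    allele_names <- sprintf("HLA*%02d:01", seq_len(n_alleles))
  if (anyDuplicated(allele_names)) stop("duplicate allele names")
  if (is.null(risk_alleles)) risk_alleles <- allele_names[1]
  stopifnot(all(risk_alleles %in% allele_names))
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ref <- sample(aa, length, replace = TRUE)
  seqs <- matrix(rep(ref, n_alleles), nrow = n_alleles, byrow = TRUE,
                 dimnames = list(allele_names, NULL))
  for (i in seq_len(n_alleles)) {
    mut <- which(stats::runif(length) < mutation_rate)
    if (base::length(mut))
      seqs[i, mut] <- sample(aa, base::length(mut), replace = TRUE)
  }
  is_risk <- allele_names %in% risk_alleles
  for (r in seq_len(nrow(risk_positions))) {
    pos <- risk_positions$position[r]
    res <- risk_positions$residue[r]
    alt <- setdiff(aa, res)[1]
    seqs[is_risk, pos] <- res
    seqs[!is_risk, pos] <- alt
  }
  apply(seqs, 1, paste, collapse = "")
}
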