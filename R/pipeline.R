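#' Pipeline configuration
#'
#' Collects stage toggles, every analysis threshold, the simulation
#' configuration and the output directory. Defaults mirror the study
#' conventions: tiers at 5e-8 / 1e-6 / FDR 0.05, stepwise entry/exit 0.001
#' (regional) and 0.01 (HLA), sliding windows of 20 unweighted counts and 4
#' weighted units, LD pruning at r^2 < 0.2, eQTL proxies at r^2 >= 0.5.
#'
#' @param sim a [sim_config()] for the synthetic cohort.
#' @param out_dir artifact directory.
#' @param stages character vector of stages to run (order fixed internally).
#' @param thresholds a [qc_thresholds()].
#' @param tier1,tier2,fdr significance tiers.
#' @param stepwise_regional,stepwise_hla entry/exit criteria.
#' @param window_unweighted,window_weighted sliding-window widths.
#' @param eqtl_r2 proxy threshold.
#' @param n_factors admixture factors per ancestry (named vector or single).
#' @param n_test_cases,n_test_controls held-out split for the load analysis.
#' @param region_kb region-grouping distance for reporting (kb).
#' @param write_genotypes also write the full genotype matrix and VCF
#'   (large; off by default).
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = tempfile("transload_run_"),
                            stages = c("synth", "qc", "assoc", "meta", "hla",
                                       "genload", "ancprofile", "annotate"),
                            thresholds = qc_thresholds(),
                            tier1 = 5e-8, tier2 = 1e-6, fdr = 0.05,
                            stepwise_regional = 0.001, stepwise_hla = 0.01,
                            window_unweighted = 20, window_weighted = 4,
                            eqtl_r2 = 0.5, n_factors = 2L,
                            n_test_cases = 500L, n_test_controls = 500L,
                            region_kb = 250, write_genotypes = FALSE,
                            seed = 1L) {
  stopifnot(tier1 > 0, tier2 > 0, fdr > 0, stepwise_regional > 0,
            stepwise_hla > 0, window_unweighted > 0, window_weighted > 0)
  structure(list(sim = sim, out_dir = out_dir, stages = stages,
                 thresholds = thresholds, tier1 = tier1, tier2 = tier2,
                 fdr = fdr, stepwise_regional = stepwise_regional,
                 stepwise_hla = stepwise_hla,
                 window_unweighted = window_unweighted,
                 window_weighted = window_weighted, eqtl_r2 = eqtl_r2,
                 n_factors = n_factors, n_test_cases = n_test_cases,
                 n_test_controls = n_test_controls, region_kb = region_kb,
                 write_genotypes = write_genotypes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Demonstration pipeline configuration
#'
#' The reference end-to-end demonstration: three admixed cohorts of about
#' 4,000 samples each (EA-like 2,000/2,000; AA- and HA-like 1,000/1,000), a
#' 2,000-SNP panel with 40 causal SNPs of modest effect, a small
#' supra-additive load term, and earlier onset with higher weighted load.
#'
#' @param out_dir artifact directory.
#' @param seed global seed.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(out_dir = tempfile("transload_demo_"), seed = 1L) {
  m <- 2000L
  set.seed(child_seed(seed, 9L))
  beta <- numeric(m)
  causal <- sample.int(m, 40)
  beta[causal] <- log(stats::runif(40, 1.15, 1.6))
  base <- stats::runif(m, 0.05, 0.5)
  raf <- sapply(1:3, function(i)
    pmin(pmax(base + stats::rnorm(m, 0, 0.08), 0.02), 0.98))
  theta <- 0.005
  # centre the baseline logit so the population prevalence sits near 50%
  var_load <- sum(2 * rowMeans(raf)[causal] * (1 - rowMeans(raf)[causal]))
  b0 <- -mean(colSums(2 * raf[causal, ] * beta[causal])) - theta * var_load
  pipeline_config(
    sim = sim_config(n_cases = c(EA = 2000, AA = 1000, HA = 1000),
                     n_controls = c(EA = 2000, AA = 1000, HA = 1000),
                     n_snps = m, raf = raf, beta = beta, theta = theta,
                     b0 = b0, age_load_slope = -2),
    out_dir = out_dir, seed = seed)
}

run_assoc_table <- function(genotypes, phenotype, covariates, snp_ids) {
  out <- vector("list", length(snp_ids))
  for (j in seq_along(snp_ids))
    out[[j]] <- test_snp(genotypes[, snp_ids[j]], phenotype, covariates,
                         snp_id = snp_ids[j])
  do.call(rbind, out)
}

#' Run the full synthetic-cohort pipeline
#'
#' Stages run in order synth, qc, assoc (per ancestry), meta, hla, genload,
#' ancprofile, annotate; each writes a TSV under `out_dir`, and a manifest of
#' content hashes plus a log (seed, package version) are written at the end.
#' Reruns under the same config are byte-identical apart from the log
#' timestamp. Stages absent from `config$stages` are skipped; downstream
#' stages that do not need them still run.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory stage results; `$out_dir` holds
#'   the artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  meta_hdr <- c(seed = config$seed, tier1 = config$tier1,
                tier2 = config$tier2, fdr = config$fdr)
  art <- list(out_dir = config$out_dir)
  stage_on <- function(s) s %in% config$stages
  emit <- function(df, name, extra = NULL)
    write_result_tsv(df, file.path(config$out_dir, paste0(name, ".tsv")),
                     c(meta_hdr, extra))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## synth ------------------------------------------------------------------
  cohort <- run_stage("synth", {
    ch <- simulate_cohort(config$sim, seed = config$seed)
    ch$hla <- simulate_hla(config$sim, ch$samples, seed = config$seed)
    ch$ann <- simulate_annotations(ch$snps, seed = config$seed)
    ch$proteins <- simulate_hla_proteins(
      n_alleles = 8, length = 120,
      risk_positions = data.frame(position = c(47, 71),
                                  residue = c("F", "A")),
      risk_alleles = c("HLA*01:01", "HLA*02:01"), seed = config$seed)
    ch
  })
  art$cohort <- cohort
  emit(cohort$samples, "samples")
  emit(cohort$snps, "snps")
  if (config$write_genotypes) {
    write_genotypes_tsv(cohort$genotypes,
                        file.path(config$out_dir, "genotypes.tsv"))
    write_vcf(cohort$genotypes, cohort$snps,
              file.path(config$out_dir, "genotypes.vcf"))
  }
  write_fasta(cohort$proteins, file.path(config$out_dir, "hla_proteins.fasta"))

  ancestries <- config$sim$ancestries
  samples <- cohort$samples
  G <- cohort$genotypes

  ## qc ---------------------------------------------------------------------
  if (stage_on("qc")) art$qc <- run_stage("qc", {
    qc <- list()
    for (a in ancestries) {
      idx <- samples$ancestry == a
      g <- G[idx, , drop = FALSE]
      keep_samp <- run_sample_qc(g, config$thresholds)
      g <- g[keep_samp, , drop = FALSE]
      y <- samples$status[match(keep_samp, samples$sample_id)]
      snp_qc <- run_snp_qc(g, y, config$thresholds)
      pruned <- ld_prune(g[, snp_qc$keep, drop = FALSE],
                         config$thresholds$ld_r2_max)
      adm <- as.matrix(samples[match(keep_samp, samples$sample_id),
                               c("admix_CEU", "admix_YRI", "admix_CHB")])
      factors <- admixture_factors(adm, config$n_factors)
      qc[[a]] <- list(samples = keep_samp, snps = snp_qc$keep,
                      report = snp_qc$report, pruned = pruned,
                      factors = factors, phenotype = y)
    }
    qc$union <- union_test_count(lapply(qc[ancestries],
                                        function(x) x$pruned))
    emit(do.call(rbind, lapply(ancestries, function(a) {
      r <- qc[[a]]$report; r$ancestry <- a; r
    })), "qc_snps", c(union_m = qc$union$m))
    qc
  })

  ## assoc ------------------------------------------------------------------
  if (stage_on("assoc") && !is.null(art$qc)) art$assoc <- run_stage("assoc", {
    assoc <- list()
    for (a in ancestries) {
      q <- art$qc[[a]]
      g <- G[q$samples, q$snps, drop = FALSE]
      tab <- run_assoc_table(g, q$phenotype, q$factors, q$snps)
      tiers <- assign_tiers(pmax(tab$p, 1e-300))
      tab$fdr_adjusted_p <- tiers$fdr_adjusted_p
      tab$tier <- tiers$tier
      # genomic control on the primary additive statistics (calibrated null)
      p_gc <- ifelse(is.na(tab$p_additive), tab$p, tab$p_additive)
      chisq <- stats::qchisq(pmax(p_gc, 1e-300), df = 1,
                             lower.tail = FALSE)
      gc <- genomic_control(chisq[!is.na(chisq)],
                            sum(q$phenotype == 1), sum(q$phenotype == 0))
      tab$ancestry <- a
      assoc[[a]] <- list(table = tab, gc = gc)
    }
    emit(do.call(rbind, lapply(assoc, `[[`, "table")), "assoc")
    emit(data.frame(ancestry = ancestries,
                    lambda_gc = sapply(assoc, function(x) x$gc$lambda_gc),
                    lambda_1000 = sapply(assoc,
                                         function(x) x$gc$lambda_1000)),
         "genomic_control")
    assoc
  })

  ## meta -------------------------------------------------------------------
  if (stage_on("meta") && !is.null(art$assoc)) art$meta <- run_stage("meta", {
    tabs <- lapply(art$assoc, `[[`, "table")
    shared <- Reduce(intersect, lapply(tabs, function(t)
      t$snp_id[!is.na(t$p)]))
    rows <- lapply(shared, function(s) {
      per <- lapply(ancestries, function(a)
        tabs[[a]][tabs[[a]]$snp_id == s, ])
      per <- do.call(rbind, per)
      n_coh <- sapply(ancestries, function(a)
        length(art$qc[[a]]$samples))
      mi <- meta_input(per$ancestry, pmin(pmax(per$p, 1e-300), 1 - 1e-16),
                       ifelse(per$beta >= 0, 1, -1), n_coh)
      mr <- inverse_normal_meta(mi)
      qh <- cochran_q(per$beta, per$se)
      data.frame(snp_id = s, z = mr$z_combined, p_meta = mr$p_combined,
                 q = qh$q, q_p = qh$p, stringsAsFactors = FALSE)
    })
    mt <- if (length(rows)) do.call(rbind, rows) else
      data.frame(snp_id = character(), z = numeric(), p_meta = numeric(),
                 q = numeric(), q_p = numeric())
    emit(mt, "meta")
    mt
  })

  ## hla --------------------------------------------------------------------
  if (stage_on("hla")) art$hla <- run_stage("hla", {
    hla <- list()
    drb1 <- cohort$hla[cohort$hla$locus == "DRB1", ]
    for (a in ancestries) {
      ids <- if (is.null(art$qc)) samples$sample_id[samples$ancestry == a]
      else art$qc[[a]]$samples
      d <- cohort$hla[cohort$hla$sample_id %in% ids, ]
      y <- stats::setNames(samples$status, samples$sample_id)[ids]
      fac <- if (is.null(art$qc)) NULL else art$qc[[a]]$factors
      counts <- hla_allele_counts(d, y)
      M <- dosage_matrix(d, "dosage")
      single <- do.call(rbind, lapply(seq_len(ncol(M)), function(j) {
        cnt <- counts[counts$allele == colnames(M)[j], ]
        r <- allele_association(M[, j], unname(y), fac,
                                allele = colnames(M)[j],
                                best_guess_cases = cnt$count_cases,
                                best_guess_controls = cnt$count_controls)
        r$cohort <- a
        r
      }))
      step <- hla_stepwise(d, y, fac, p_enter = config$stepwise_hla,
                           p_exit = config$stepwise_hla)
      ch <- compound_het(M[, "DRB1*03:01"], M[, "DRB1*15:01"], unname(y),
                         fac)
      hla[[a]] <- list(single = single, stepwise = step,
                       compound_het = ch)
    }
    singles <- do.call(rbind, lapply(hla[ancestries], `[[`, "single"))
    emit(singles, "hla_single_allele")
    # protein clustering with the association overlay
    assoc_overlay <- data.frame(allele = singles$allele,
                                cohort = singles$cohort,
                                or_point = singles$or_point, p = singles$p)
    prot <- cohort$proteins
    # map simulated protein names onto DRB1 allele names where they coincide
    tree <- build_nj_tree(prot, NULL)
    writeLines(tree$newick, file.path(config$out_dir, "hla_tree.nwk"))
    hla$tree <- tree
    hla$overlay <- assoc_overlay
    hla
  })

  ## genload ----------------------------------------------------------------
  if (stage_on("genload") && !is.null(art$qc)) art$genload <-
    run_stage("genload", {
      a1 <- ancestries[1]   # EA-like discovery cohort
      q <- art$qc[[a1]]
      y_all <- stats::setNames(samples$status, samples$sample_id)
      split <- split_train_test(q$samples, unname(y_all[q$samples]),
                                config$n_test_cases, config$n_test_controls,
                                seed = config$seed)
      fac_of <- function(ids) q$factors[match(ids, q$samples), , drop = FALSE]
      w <- select_training_weights(G[split$train, q$snps, drop = FALSE],
                                   unname(y_all[split$train]),
                                   fac_of(split$train),
                                   regions = cohort$snps$chr[
                                     match(q$snps, cohort$snps$snp_id)],
                                   fdr = config$fdr)
      gl <- list(split = split, weights = w)
      if (!nrow(w)) {
        gl$note <- "no training SNPs passed FDR; load analysis skipped"
      } else {
        test_ids <- split$test
        y_test <- unname(y_all[test_ids])
        fac_test <- fac_of(test_ids)
        for (mode in c("unweighted", "weighted")) {
          grs <- compute_grs(G[test_ids, , drop = FALSE], w, mode)
          width <- if (mode == "unweighted") config$window_unweighted else
            config$window_weighted
          step <- if (mode == "unweighted") 1 else {
            dg <- min(diff(sort(unique(w$gamma))), na.rm = TRUE)
            if (!is.finite(dg) || dg <= 0) 0.05 else max(dg, 0.05)
          }
          sw <- tryCatch(sliding_window_or(grs$load, y_test, fac_test,
                                           window_width = width,
                                           step = step),
                         error = function(e) NULL)
          ev <- evaluate_grs(grs$load, y_test, fac_test, mode)
          nl <- nonlinearity_test(grs$load, y_test, fac_test)
          gl[[mode]] <- list(grs = grs, windows = sw, evaluation = ev,
                             nonlinearity = nl)
        }
        cases_t <- test_ids[y_all[test_ids] == 1]
        ages <- samples$age_dx[match(cases_t, samples$sample_id)]
        wload <- gl$weighted$grs$load[match(cases_t, test_ids)]
        gl$age_onset <- tryCatch(
          age_onset_association(wload, ages, fac_of(cases_t)),
          error = function(e) list(error = conditionMessage(e)))
        emit(do.call(rbind, lapply(c("unweighted", "weighted"), function(m)
          cbind(mode = m, gl[[m]]$evaluation[-1]))), "load_evaluation")
        if (!is.null(gl$unweighted$windows))
          emit(gl$unweighted$windows$windows, "load_windows_unweighted")
        if (!is.null(gl$weighted$windows))
          emit(gl$weighted$windows$windows, "load_windows_weighted")
      }
      emit(w, "load_weights")
      gl
    })

  ## ancprofile -------------------------------------------------------------
  if (stage_on("ancprofile") && !is.null(art$assoc)) art$ancprofile <-
    run_stage("ancprofile", {
      # risk alleles: FDR-significant SNPs of the discovery cohort
      t1 <- art$assoc[[ancestries[1]]]$table
      risk <- t1$snp_id[!is.na(t1$fdr_adjusted_p) &
                          t1$fdr_adjusted_p < config$fdr]
      prof <- list(risk_snps = risk)
      if (length(risk) >= 3) {
        raf <- sapply(ancestries, function(a) {
          q <- art$qc[[a]]
          cases <- q$samples[q$phenotype == 1]
          gg <- G[cases, risk, drop = FALSE]
          beta_sign <- sign(t1$beta[match(risk, t1$snp_id)])
          raf_coded <- colMeans(gg, na.rm = TRUE) / 2
          ifelse(beta_sign >= 0, raf_coded, 1 - raf_coded)
        })
        rownames(raf) <- risk
        colnames(raf) <- ancestries
        names(colnames(raf)) <- NULL
        clus_col <- if ("AA" %in% ancestries) "AA" else ancestries[2]
        prof$clusters <- cluster_case_raf(raf, 3, seed = config$seed,
                                          aa_col = clus_col)
        emit(prof$clusters, "raf_clusters")
      }
      a_dev <- if ("AA" %in% ancestries) "AA" else ancestries[2]
      q <- art$qc[[a_dev]]
      cases <- q$samples[q$phenotype == 1]
      if (length(risk) >= 2 && length(cases) >= 30) {
        adm <- as.matrix(samples[match(cases, samples$sample_id),
                                 c("admix_CEU", "admix_YRI", "admix_CHB")])
        colnames(adm) <- c("CEU", "YRI", "CHB")
        t1r <- t1[match(risk, t1$snp_id), ]
        prof$deviation <- admixture_deviation(
          G[cases, risk, drop = FALSE], adm,
          risk_is_coded = t1r$beta >= 0)
        emit(prof$deviation$deviations, "admixture_deviation")
      }
      prof
    })

  ## annotate ---------------------------------------------------------------
  if (stage_on("annotate")) art$annotate <- run_stage("annotate", {
    ann <- biological_score_table(cohort$ann$annotations)
    fl <- cohort$ann$flanks
    cpg <- do.call(rbind, lapply(seq_len(nrow(fl)), function(i) {
      f <- cpg_flags(fl$left_base[i],
                     c(cohort$snps$allele_risk[i],
                       cohort$snps$allele_other[i]), fl$right_base[i])
      data.frame(snp_id = fl$snp_id[i],
                 risk_creates_cpg = f$creates_cpg[1],
                 risk_breaks_cpg = f$breaks_cpg[1])
    }))
    targets <- if (!is.null(art$assoc)) {
      t1 <- art$assoc[[ancestries[1]]]$table
      t1$snp_id[t1$tier %in% c("1", "2")]
    } else cohort$snps$snp_id
    ld_pairs <- data.frame(snp_id = character(), proxy_id = character(),
                           r2 = numeric())
    ej <- eqtl_proxy_join(targets, ld_pairs, cohort$ann$eqtl,
                          config$eqtl_r2)
    emit(merge(ann, cpg, by = "snp_id"), "annotation_scores")
    emit(ej, "eqtl_join")
    list(scores = ann, cpg = cpg, eqtl_join = ej)
  })

  ## manifest + log ---------------------------------------------------------
  outs <- list.files(config$out_dir, full.names = TRUE)
  outs <- outs[!basename(outs) %in% c("manifest.tsv", "log.txt")]
  manifest <- data.frame(file = basename(outs),
                         md5 = unname(tools::md5sum(outs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("timestamp: %s", format(Sys.time())),
               sprintf("seed: %d", config$seed),
               sprintf("package: transload %s",
                       as.character(utils::packageVersion("transload"))),
               sprintf("stages: %s", paste(config$stages, collapse = ","))),
             file.path(config$out_dir, "log.txt"))
  art$manifest <- manifest
  invisible(art)
}

group_regions <- function(chr, pos, gap_kb = 250) {
  o <- order(chr, pos)
  region <- integer(length(chr))
  rid <- 0L; last_chr <- NA; last_pos <- -Inf
  for (i in o) {
    if (!identical(chr[i], last_chr) || pos[i] - last_pos > gap_kb * 1000) {
      rid <- rid + 1L
    }
    region[i] <- rid
    last_chr <- chr[i]; last_pos <- pos[i]
  }
  region
}

#' Summary report tables from pipeline artifacts
#'
#' Produces the per-ancestry tier-count table (distinct regions per
#' significance tier, regions grouped by an inter-SNP distance rule), the
#' top-hit table (best SNP per region with OR/CI/P), and the load-evaluation
#' table when the load stage ran.
#'
#' @param artifacts the list returned by [run_pipeline()].
#' @param region_kb region-grouping distance (kb).
#' @return list of data.frames `tier_counts`, `top_hits`, `load_table`.
#' @export
make_report <- function(artifacts, region_kb = 250) {
  snps <- artifacts$cohort$snps
  tier_counts <- NULL; top_hits <- NULL
  if (!is.null(artifacts$assoc)) {
    tabs <- lapply(artifacts$assoc, `[[`, "table")
    tier_counts <- do.call(rbind, lapply(names(tabs), function(a) {
      t <- tabs[[a]]
      t <- t[t$tier %in% c("1", "2", "3"), , drop = FALSE]
      if (!nrow(t)) return(data.frame(ancestry = a, tier1 = 0L, tier2 = 0L,
                                      tier3 = 0L))
      idx <- match(t$snp_id, snps$snp_id)
      reg <- group_regions(snps$chr[idx], snps$pos[idx], region_kb)
      cnt <- function(tt) length(unique(reg[t$tier == tt]))
      data.frame(ancestry = a, tier1 = cnt("1"), tier2 = cnt("2"),
                 tier3 = cnt("3"))
    }))
    top_hits <- do.call(rbind, lapply(names(tabs), function(a) {
      t <- tabs[[a]]
      t <- t[!is.na(t$p) & t$tier %in% c("1", "2", "3"), , drop = FALSE]
      if (!nrow(t)) return(NULL)
      idx <- match(t$snp_id, snps$snp_id)
      reg <- group_regions(snps$chr[idx], snps$pos[idx], region_kb)
      keep <- unlist(lapply(split(seq_len(nrow(t)), reg), function(ix)
        ix[which.min(t$p[ix])]))
      cbind(ancestry = a, t[keep, c("snp_id", "model_used", "or_point",
                                    "ci_lo", "ci_hi", "p", "tier")])
    }))
  }
  load_table <- NULL
  gl <- artifacts$genload
  if (!is.null(gl) && !is.null(gl$unweighted)) {
    load_table <- do.call(rbind, lapply(c("unweighted", "weighted"),
                                        function(m) gl[[m]]$evaluation))
  }
  list(tier_counts = tier_counts, top_hits = top_hits,
       load_table = load_table)
}
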