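make_hla_cohort <- function(n = 3000, seed = 40, logits = NULL) {
  args <- list(n_cases = c(EA = n / 2), n_controls = c(EA = n / 2),
               n_snps = 5, dosage_noise_sd = 0.05)
  if (!is.null(logits)) args$hla_genotype_logits <- logits
  cfg <- do.call(sim_config, args)
  ch <- simulate_cohort(cfg, seed = seed)
  hla <- simulate_hla(cfg, ch$samples, seed = seed)
  list(cfg = cfg, ch = ch, hla = hla)
}

test_that("allele association gates on best-guess counts and scales with dosage", {
  r <- allele_association(runif(100, 0, 2), rbinom(100, 1, 0.5),
                          allele = "rare", best_guess_cases = 9,
                          best_guess_controls = 9)
  expect_true(is.na(r$p))
  expect_match(r$note, "min count 10")
  # dosage equal to twice a carrier indicator: slope is half the carrier beta
  set.seed(41)
  carrier <- rbinom(2000, 1, 0.3)
  y <- rbinom(2000, 1, plogis(-0.5 + 0.8 * carrier))
  r_carrier <- allele_association(carrier, y, allele = "c")
  r_double <- allele_association(2 * carrier, y, allele = "d")
  expect_equal(r_double$beta, r_carrier$beta / 2, tolerance = 1e-8)
  r_const <- allele_association(rep(1, 100), rbinom(100, 1, 0.5))
  expect_match(r_const$note, "constant")
})

test_that("a planted allele effect is estimated and covered", {
  x <- make_hla_cohort(4000, seed = 42)
  M <- dosage_matrix(x$hla[x$hla$locus == "DRB1", ])
  y <- x$ch$samples$status[match(rownames(M), x$ch$samples$sample_id)]
  r <- allele_association(M[, "DRB1*03:01"], y, allele = "DRB1*03:01")
  expect_lt(r$p, 0.01)
  expect_gt(r$beta, 0)
})

test_that("stepwise HLA modelling keeps conditional P below the entry bar", {
  x <- make_hla_cohort(3000, seed = 43)
  y <- setNames(x$ch$samples$status, x$ch$samples$sample_id)
  step <- hla_stepwise(x$hla, y)
  expect_true(all(step$conditional$p < 0.01))
  # risk alleles planted through the haplotype logits are found
  expect_true(any(c("DRB1*03:01", "DRB1*15:01") %in% step$selected))
  # fixed point: rerunning on the final model changes nothing
  M <- dosage_matrix(x$hla, "dosage")
  if (length(step$selected) > 1) {
    again <- regional_stepwise(M[, step$selected, drop = FALSE], unname(y),
                               p_enter = 0.01, p_exit = 0.01)
    expect_setequal(again$selected, step$selected)
  }
  # null table: no alleles selected
  x0 <- make_hla_cohort(1500, seed = 44,
                        logits = setNames(rep(0, 6),
                                          c("0/0", "dr3_het", "dr15_het",
                                            "dr3_hom", "dr15_hom",
                                            "compound_het")))
  y0 <- setNames(x0$ch$samples$status, x0$ch$samples$sample_id)
  step0 <- hla_stepwise(x0$hla, y0)
  expect_lte(length(step0$selected), 1)
})

test_that("SNP-given-HLA adjustment removes mediated signals, keeps direct ones", {
  set.seed(45)
  n <- 4000
  dose <- rbinom(n, 2, 0.25) + rnorm(n, 0, 0.05)
  dose <- pmin(pmax(dose, 0), 2)
  # SNP tagging the allele (high correlation), no direct effect
  g_tag <- round(dose) + ifelse(runif(n) < 0.03, sample(c(-1, 1), n, TRUE), 0)
  g_tag <- pmin(pmax(g_tag, 0), 2)
  y <- rbinom(n, 1, plogis(-1 + 0.6 * dose))
  unadj <- test_snp(g_tag, y, snp_id = "tag")
  adj <- snp_given_hla(g_tag, cbind(dose), y, snp_id = "tag")
  expect_lt(unadj$p, 1e-4)
  expect_gt(adj$p, 0.001)
  expect_gt(adj$p, unadj$p)
  # independent SNP with a direct effect survives adjustment
  g_ind <- rbinom(n, 2, 0.3)
  y2 <- rbinom(n, 1, plogis(-1 + 0.4 * g_ind + 0.6 * dose))
  unadj2 <- test_snp(g_ind, y2, snp_id = "ind")
  adj2 <- snp_given_hla(g_ind, cbind(dose), y2, snp_id = "ind")
  expect_lt(adj2$p, 1e-4)
  expect_lt(abs(adj2$beta - unadj2$beta) / abs(unadj2$beta), 0.25)
  # no selected alleles: identical to the plain test
  plain <- test_snp(g_ind, y2, snp_id = "ind")
  none <- snp_given_hla(g_ind, matrix(numeric(0), n, 0), y2, snp_id = "ind")
  expect_equal(none$p, plain$p)
})

test_that("compound heterozygote class is classified and contrasted", {
  x <- make_hla_cohort(4000, seed = 46)
  M <- dosage_matrix(x$hla[x$hla$locus == "DRB1", ])
  y <- x$ch$samples$status[match(rownames(M), x$ch$samples$sample_id)]
  ch <- compound_het(M[, "DRB1*03:01"], M[, "DRB1*15:01"], y)
  expect_equal(sum(ch$classes), length(y))
  expect_true(all(c("compound_het vs dr3_hom", "compound_het vs dr15_hom")
                  %in% ch$het_vs_hom$contrast))
  expect_equal(nrow(ch$genotypic), 5)
  # degenerate: everyone 0/0 completes with contrasts absent
  ch0 <- compound_het(rep(0, 100), rep(0, 100), rbinom(100, 1, 0.5))
  expect_equal(ch0$note, "insufficient genotype classes")
  expect_true(is.na(ch0$interaction_p))
})

test_that("dominance lack-of-fit is near-nominal under additive allele effects", {
  set.seed(47)
  rej <- replicate(60, {
    n <- 1200
    d3 <- rbinom(n, 2, 0.2); d15 <- rbinom(n, 2, 0.15)
    y <- rbinom(n, 1, plogis(-0.8 + 0.4 * d3 + 0.3 * d15))
    compound_het(d3, d15, y)$dominance_lof["dr3"] < 0.05
  })
  expect_equal(mean(rej), 0.05, tolerance = 0.07)
})

test_that("HLA interaction Wald tests are symmetric and flag inestimable rows", {
  set.seed(48)
  n <- 3000
  dose <- runif(n, 0, 2)
  sexn <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * dose * sexn))
  tab <- hla_interaction_tests(cbind(al = dose), sexn, y)
  expect_lt(tab$p, 0.05)
  # swapping the interacting terms leaves the product P unchanged
  tab_swap <- hla_interaction_tests(cbind(al = sexn), dose, y)
  expect_equal(tab$p, tab_swap$p, tolerance = 1e-8)
  # constant partner: product collinear, flagged
  tab_bad <- hla_interaction_tests(cbind(al = dose), rep(1, n), y)
  expect_true(is.na(tab_bad$p))
  expect_match(tab_bad$note, "inestimable")
})

test_that("neighbour joining reproduces additive quartets exactly", {
  seqs <- additive_quartet()
  br <- attr(seqs, "branch")
  res <- build_nj_tree(seqs)
  expect_s3_class(res$tree, "phylo")
  # cophenetic distances on an additive matrix equal the input distances
  coph <- ape::cophenetic.phylo(res$tree)[rownames(res$distances),
                                          colnames(res$distances)]
  expect_equal(coph, res$distances, tolerance = 1e-12)
  # internal edge length equals the planted shared-mutation fraction
  internal <- res$tree$edge.length[res$tree$edge[, 2] >
                                     length(res$tree$tip.label)]
  expect_equal(internal, unname(br["E"]), tolerance = 1e-12)
  # identical sequences give a zero-length cherry
  seqs2 <- c(seqs, E = unname(seqs["A"]))
  d2 <- p_distance(seqs2)
  expect_equal(d2["A", "E"], 0)
})

test_that("OR overlay honours the display threshold", {
  seqs <- additive_quartet()
  assoc <- data.frame(allele = c("A", "A", "B"), cohort = c("EA", "AA", "EA"),
                      or_point = c(1.5, 1.4, 0.8), p = c(0.001, 0.02, 0.02))
  res <- build_nj_tree(seqs, assoc, stepwise_alleles = "A")
  ann <- res$annotations
  expect_equal(ann$or_overlay[ann$allele == "A"], "EA:1.50")  # 0.02 hidden
  expect_true(is.na(ann$or_overlay[ann$allele == "B"]))
  expect_true(ann$stepwise[ann$allele == "A"])
  # fewer than three sequences: distances only
  res2 <- build_nj_tree(seqs[1:2])
  expect_null(res2$tree)
  expect_equal(dim(res2$distances), c(2, 2))
})

test_that("risk-unique residues recover planted positions with mature numbering", {
  seqs <- simulate_hla_proteins(
    8, 120, risk_positions = data.frame(position = c(47, 100),
                                        residue = c("F", "A")),
    risk_alleles = c("HLA*01:01", "HLA*02:01"), mutation_rate = 0.01,
    seed = 49)
  res <- risk_unique_residues(seqs, c("HLA*01:01", "HLA*02:01"),
                              comparison_alleles = setdiff(names(seqs),
                                                           c("HLA*01:01",
                                                             "HLA*02:01")))
  expect_true(all(c(47, 100) %in% res$position))
  expect_equal(res$residue[res$position == 47], "F")
  # signal-peptide offset: column 29 of a 29-residue peptide is position -1
  res_off <- risk_unique_residues(seqs, c("HLA*01:01", "HLA*02:01"),
                                  comparison_alleles = setdiff(names(seqs),
                                                               c("HLA*01:01",
                                                                 "HLA*02:01")),
                                  signal_peptide_length = 29)
  expect_true((47 - 29) %in% res_off$position)
  # a residue shared with any comparison allele is excluded
  seqs2 <- c(r1 = "AAF", r2 = "AAF", c1 = "AAF", c2 = "CAT")
  res2 <- risk_unique_residues(seqs2, c("r1", "r2"),
                               comparison_alleles = c("c1", "c2"))
  expect_equal(nrow(res2), 0)
  # empty comparison set is explicit
  seqs3 <- c(r1 = "AAAA", x = "CCCC")
  res3 <- risk_unique_residues(seqs3, "r1", identity_min = 0.95)
  expect_equal(nrow(res3), 0)
  expect_equal(attr(res3, "note"), "empty comparison set")
})
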