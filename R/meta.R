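#' Per-cohort inputs for the inverse-normal meta-analysis
#'
#' @param cohort labels.
#' @param p two-sided P-values in (0,1).
#' @param direction sign of the cohort effect (+1/-1).
#' @param n cohort total sample size (cases + controls).
#' @return data.frame of validated inputs.
#' @export
meta_input <- function(cohort, p, direction, n) {
  stopifnot(length(p) == length(cohort), length(direction) == length(p),
            length(n) == length(p))
  if (any(p <= 0 | p >= 1))
    stop("p-values must lie strictly in (0,1); floor extreme values before ",
         "meta-analysis (e.g. pmax(p, 1e-300))")
  stopifnot(all(direction %in% c(-1, 1)), all(n > 0))
  data.frame(cohort = cohort, p = p, direction = direction, n = n,
             stringsAsFactors = FALSE)
}

#' Sample-size-weighted inverse-normal meta-analysis
#'
#' The METAL sample-size scheme: `z_i = direction_i * qnorm(1 - p_i/2)`,
#' weights `w_i = sqrt(n_i)`, `Z = sum(w_i z_i) / sqrt(sum(w_i^2))`,
#' `p = 2 * (1 - Phi(|Z|))`. Tail evaluation is numerically stable to
#' p ~ 1e-300.
#'
#' @param inputs a [meta_input()] data.frame.
#' @return list with z_combined, p_combined, k, and per-cohort z and weights.
#' @export
inverse_normal_meta <- function(inputs) {
  if (!nrow(inputs)) stop("no cohorts")
  inputs <- meta_input(inputs$cohort, inputs$p, inputs$direction, inputs$n)
  z <- inputs$direction * stats::qnorm(inputs$p / 2, lower.tail = FALSE)
  w <- sqrt(inputs$n)
  Z <- sum(w * z) / sqrt(sum(w^2))
  p <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
  list(z_combined = Z, p_combined = p, k = nrow(inputs),
       z_cohort = stats::setNames(z, inputs$cohort),
       weights = stats::setNames(w, inputs$cohort))
}

#' Cochran's Q heterogeneity test on the log odds-ratio scale
#'
#' Fixed-effect inverse-variance mean, then `Q = sum(((b_i - b_bar)/se_i)^2)`
#' against chi-square with k - 1 df.
#'
#' @param betas per-cohort log odds ratios.
#' @param ses per-cohort standard errors (finite, > 0).
#' @return list with q, df, p, beta_fixed; for a single cohort q/p are NA.
#' @export
cochran_q <- function(betas, ses) {
  stopifnot(length(betas) == length(ses))
  if (length(betas) < 2)
    return(list(q = NA_real_, df = NA_integer_, p = NA_real_,
                beta_fixed = if (length(betas)) betas[1] else NA_real_))
  stopifnot(all(is.finite(ses)), all(ses > 0), all(is.finite(betas)))
  w <- 1 / ses^2
  b_fixed <- sum(w * betas) / sum(w)
  q <- sum(((betas - b_fixed) / ses)^2)
  df <- length(betas) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       beta_fixed = b_fixed)
}

#' Published cohort descriptors used by the worked examples
#'
#' Per-ancestry case/control counts of the transancestral study the pipeline
#' mirrors, and the four meta-analysis rows (per-ancestry P, effect
#' direction) used as desk-scale worked examples.
#'
#' @return list with `cohorts` (data.frame ancestry/cases/controls/n) and
#'   `worked_rows` (list of meta_input data.frames keyed by SNP, with the
#'   reported meta P attached as attribute `reported_p`).
#' @export
reference_study <- function() {
  cohorts <- data.frame(
    ancestry = c("EA", "AA", "HA"),
    cases = c(6748L, 2970L, 1872L),
    controls = c(11516L, 2452L, 2016L))
  cohorts$n <- cohorts$cases + cohorts$controls
  n <- stats::setNames(cohorts$n, cohorts$ancestry)
  row <- function(p, dir, reported) {
    x <- meta_input(cohort = c("EA", "AA", "HA"), p = p,
                    direction = dir, n = n[c("EA", "AA", "HA")])
    attr(x, "reported_p") <- reported
    x
  }
  worked <- list(
    rs3733345  = row(c(5.84e-8, 3.56e-3, 7.03e-3), c(-1, -1, -1), 1.83e-11),
    rs3828069  = row(c(3.37e-6, 3.13e-2, 6.43e-4), c(-1, -1, -1), 1.77e-9),
    rs34840245 = row(c(4.03e-6, 9.06e-5, 1.47e-3), c(1, 1, 1), 2.37e-11),
    rs223889   = row(c(1.16e-4, 5.56e-3, 3.22e-4), c(1, 1, 1), 1.08e-8))
  list(cohorts = cohorts, worked_rows = worked)
}
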