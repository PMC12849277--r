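# Two-step mediation bookkeeping: double-FDR screening, product-of-
# coefficients mediation with delta-method SEs, Monte Carlo confidence
# intervals, proportions mediated, and between-cluster contrasts.

#' Screen mediator candidates by double FDR
#'
#' Step-1 p-values (cluster-scaled exposure -> mediator) are FDR-corrected
#' within each cluster across the panel; step-2 p-values (mediator ->
#' outcome) across the panel. A (cluster, mediator) pair is a candidate
#' iff both q-values fall below `alpha`. Mediators present in step 1 but
#' absent from step 2 are excluded and logged. Setting
#' `pooled_step1 = TRUE` corrects step 1 as a single family instead.
#'
#' @param step1 Data.frame with columns cluster, protein, beta, se, p.
#' @param step2 Data.frame with columns protein, beta, se, p.
#' @param alpha q-value threshold (default 0.05).
#' @param pooled_step1 Correct step 1 as one family (default FALSE:
#'   per-cluster families).
#' @return List with `candidates` (data.frame cluster, protein, beta1,
#'   se1, q1, beta2, se2, q2), `step1` and `step2` (inputs with q
#'   columns), and `excluded` (proteins missing from step 2).
#' @export
screen_mediators <- function(step1, step2, alpha = 0.05, pooled_step1 = FALSE) {
  step2$q <- bh_fdr(step2$p)
  if (pooled_step1) {
    step1$q <- bh_fdr(step1$p)
  } else {
    step1$q <- NA_real_
    for (cl in unique(step1$cluster)) {
      i <- step1$cluster == cl
      step1$q[i] <- bh_fdr(step1$p[i])
    }
  }
  excluded <- setdiff(unique(step1$protein), step2$protein)
  if (length(excluded) > 0)
    message("screen_mediators: ", length(excluded),
            " protein(s) absent from step 2; excluded")
  s1 <- step1[step1$protein %in% step2$protein, , drop = FALSE]
  j <- match(s1$protein, step2$protein)
  hit <- s1$q < alpha & step2$q[j] < alpha
  candidates <- data.frame(
    cluster = s1$cluster[hit], protein = s1$protein[hit],
    beta1 = s1$beta[hit], se1 = s1$se[hit], q1 = s1$q[hit],
    beta2 = step2$beta[j][hit], se2 = step2$se[j][hit], q2 = step2$q[j][hit],
    stringsAsFactors = FALSE
  )
  rownames(candidates) <- NULL
  list(candidates = candidates, step1 = step1, step2 = step2,
       excluded = excluded)
}

#' Product-of-coefficients mediated effect
#'
#' mediated = beta1 * beta2, with the first-order delta-method SE
#' sqrt(beta1^2 se2^2 + beta2^2 se1^2).
#'
#' @param beta1,se1 Exposure -> mediator estimate and SE.
#' @param beta2,se2 Mediator -> outcome estimate and SE.
#' @return List with mediated, se.
#' @export
product_of_coefficients <- function(beta1, se1, beta2, se2) {
  stopifnot(all(se1 > 0), all(se2 > 0))
  list(mediated = beta1 * beta2,
       se = sqrt(beta1^2 * se2^2 + beta2^2 * se1^2))
}

#' Monte Carlo confidence interval for a product of two estimates
#'
#' Draws b1* ~ Normal(beta1, se1^2) and b2* ~ Normal(beta2, se2^2)
#' independently and returns the empirical (1-level)/2 and 1-(1-level)/2
#' quantiles of b1* b2*. With a fixed seed the interval is bit-identical
#' across runs.
#'
#' @param beta1,se1,beta2,se2 The two estimates and their SEs.
#' @param draws Number of Monte Carlo draws (>= 10000; default 1e6).
#' @param seed Integer seed.
#' @param level Coverage level (default 0.95).
#' @return List with lower, upper, level, draws, seed.
#' @export
monte_carlo_ci <- function(beta1, se1, beta2, se2, draws = 1e6, seed = 1L,
                           level = 0.95) {
  if (draws < 1e4) stop("draws must be at least 10,000")
  set.seed(seed)
  prod <- stats::rnorm(draws, beta1, se1) * stats::rnorm(draws, beta2, se2)
  qs <- stats::quantile(prod, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, draws = draws, seed = seed)
}

#' Proportion of the total effect that is mediated
#'
#' mediated / total, stored signed: a negative proportion means the
#' mediator works against the cluster's total effect. Reports format the
#' magnitude as a percentage with a direction label.
#'
#' @param mediated Mediated (indirect) effect.
#' @param total The cluster's total exposure -> outcome MR estimate.
#' @return Signed fraction.
#' @export
proportion_mediated <- function(mediated, total) {
  if (any(total == 0)) stop("total effect is 0; proportion undefined")
  mediated / total
}

#' Z-test for the difference of two independent estimates
#'
#' z = (beta1 - beta2) / sqrt(se1^2 + se2^2), two-sided normal p.
#'
#' @param beta1,se1,beta2,se2 Estimates and SEs.
#' @return List with z, p.
#' @export
z_test <- function(beta1, se1, beta2, se2) {
  stopifnot(all(se1 > 0), all(se2 > 0))
  z <- (beta1 - beta2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Between-cluster contrast of mediated effects through one mediator
#'
#' Because the mediator -> outcome estimate is shared across clusters, the
#' difference in mediated effects factorises as beta_diff * beta_P, with
#' beta_diff = betaA - betaB the difference of the cluster-specific
#' exposure -> mediator estimates. Its SE is computed by the delta method
#' for a product:
#'   se_diff     = sqrt(seA^2 + seB^2)
#'   se_contrast = sqrt(beta_diff^2 seP^2 + betaP^2 se_diff^2)
#' The Sobel-style test statistic is z = (beta_diff * betaP) /
#' se_contrast with a two-sided normal p, and a Monte Carlo CI for the
#' product beta_diff * betaP is drawn via [monte_carlo_ci()].
#'
#' @param betaA,seA Cluster A exposure -> mediator estimate.
#' @param betaB,seB Cluster B exposure -> mediator estimate.
#' @param betaP,seP Shared mediator -> outcome estimate.
#' @param draws,seed,level Monte Carlo CI controls.
#' @return List with beta_diff, se_diff, contrast (= beta_diff * betaP),
#'   se_contrast, z, p, ci_mc.
#' @export
cluster_difference <- function(betaA, seA, betaB, seB, betaP, seP,
                               draws = 1e6, seed = 1L, level = 0.95) {
  stopifnot(seA > 0, seB > 0, seP > 0)
  beta_diff <- betaA - betaB
  se_diff <- sqrt(seA^2 + seB^2)
  se_contrast <- sqrt(beta_diff^2 * seP^2 + betaP^2 * se_diff^2)
  contrast <- beta_diff * betaP
  z <- if (se_contrast > 0) contrast / se_contrast else 0
  p <- if (se_contrast > 0) 2 * stats::pnorm(-abs(z)) else 1
  ci <- monte_carlo_ci(beta_diff, se_diff, betaP, seP,
                       draws = draws, seed = seed, level = level)
  list(beta_diff = beta_diff, se_diff = se_diff,
       contrast = contrast, se_contrast = se_contrast,
       z = z, p = p, ci_mc = ci)
}

significance_tier <- function(p, ci_lower, ci_upper) {
  if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else if (ci_lower > 0 || ci_upper < 0) "°"
  else ""
}

#' Mediation results for screened candidates
#'
#' For every (cluster, mediator) candidate, computes the
#' product-of-coefficients mediated effect, its delta-method SE, a Monte
#' Carlo CI, and the signed proportion of the cluster's total effect that
#' is mediated.
#'
#' @param candidates Candidate table from [screen_mediators()].
#' @param totals Data.frame with columns cluster, beta (the cluster
#'   total-effect MR estimates).
#' @param draws,seed,level Monte Carlo CI controls; each candidate uses a
#'   distinct seed derived from `seed`.
#' @return Data.frame with cluster, protein, mediated, se_mediated,
#'   ci_lower, ci_upper, sobel_z, sobel_p, total, proportion, tier.
#' @export
mediation_results <- function(candidates, totals, draws = 1e6, seed = 1L,
                              level = 0.95) {
  rows <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    pc <- product_of_coefficients(cd$beta1, cd$se1, cd$beta2, cd$se2)
    ci <- monte_carlo_ci(cd$beta1, cd$se1, cd$beta2, cd$se2,
                         draws = draws, seed = (seed + i) %% .Machine$integer.max,
                         level = level)
    z <- pc$mediated / pc$se
    p <- 2 * stats::pnorm(-abs(z))
    total <- totals$beta[match(cd$cluster, totals$cluster)]
    prop <- if (is.na(total)) NA_real_ else proportion_mediated(pc$mediated, total)
    rows[[i]] <- data.frame(
      cluster = cd$cluster, protein = cd$protein,
      beta1 = cd$beta1, se1 = cd$se1, beta2 = cd$beta2, se2 = cd$se2,
      mediated = pc$mediated, se_mediated = pc$se,
      ci_lower = ci$lower, ci_upper = ci$upper,
      sobel_z = z, sobel_p = p,
      total = total, proportion = prop,
      tier = significance_tier(p, ci$lower, ci$upper),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cluster = character(), protein = character(),
                      beta1 = numeric(), se1 = numeric(), beta2 = numeric(),
                      se2 = numeric(), mediated = numeric(),
                      se_mediated = numeric(), ci_lower = numeric(),
                      ci_upper = numeric(), sobel_z = numeric(),
                      sobel_p = numeric(), total = numeric(),
                      proportion = numeric(), tier = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' All pairwise between-cluster contrasts for screened mediators
#'
#' @param candidates Candidate table from [screen_mediators()].
#' @param draws,seed,level Monte Carlo CI controls.
#' @return Data.frame with protein, cluster_a, cluster_b, beta_diff,
#'   se_diff, contrast, se_contrast, z, p, ci_lower, ci_upper, tier.
#' @export
cluster_contrasts <- function(candidates, draws = 1e6, seed = 1L, level = 0.95) {
  rows <- list()
  idx <- 0L
  for (prot in unique(candidates$protein)) {
    sub <- candidates[candidates$protein == prot, , drop = FALSE]
    if (nrow(sub) < 2) next
    combs <- utils::combn(nrow(sub), 2)
    for (c_i in seq_len(ncol(combs))) {
      a <- sub[combs[1, c_i], ]; b <- sub[combs[2, c_i], ]
      idx <- idx + 1L
      ct <- cluster_difference(a$beta1, a$se1, b$beta1, b$se1,
                               a$beta2, a$se2,
                               draws = draws,
                               seed = (seed + idx) %% .Machine$integer.max,
                               level = level)
      rows[[idx]] <- data.frame(
        protein = prot, cluster_a = a$cluster, cluster_b = b$cluster,
        beta_diff = ct$beta_diff, se_diff = ct$se_diff,
        contrast = ct$contrast, se_contrast = ct$se_contrast,
        z = ct$z, p = ct$p,
        ci_lower = ct$ci_mc$lower, ci_upper = ct$ci_mc$upper,
        tier = significance_tier(ct$p, ct$ci_mc$lower, ct$ci_mc$upper),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(), cluster_a = character(),
                      cluster_b = character(), beta_diff = numeric(),
                      se_diff = numeric(), contrast = numeric(),
                      se_contrast = numeric(), z = numeric(), p = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      tier = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
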