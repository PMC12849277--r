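# Synthetic-data generator emulating the study design: an exposure GWAS
# meta-analysed from two sub-studies, an outcome GWAS, per-variant ratio
# effects structured as substantive clusters + null mass + junk outliers,
# a protein panel with a configurable mediation architecture, and an
# individual-level cohort with a two-sample split.

NONPALINDROMIC_PAIRS <- matrix(c(
  "A", "G",  "A", "C",  "G", "A",  "C", "A",
  "T", "G",  "T", "C",  "G", "T",  "C", "T"
), ncol = 2, byrow = TRUE)

#' Build a simulation configuration
#'
#' Defaults describe the reference scenario the package is calibrated
#' against: three substantive clusters of 24, 73 and 7 variants with
#' ratio-effect means 0.98, -0.61 and -1.74, a null mass of 360 variants,
#' an exposure GWAS meta-analysed from sub-studies of 266,130 and 322,154
#' individuals, an outcome GWAS of 247,173, a cohort of 194,682 women at
#' 8.5% outcome prevalence, and a 2,922-protein panel. Per-variant
#' exposure effect magnitudes are uniform on \[0.02, 0.08\] trait-SD
#' units with random signs and allele frequencies uniform on
#' \[0.1, 0.9\]: every generated variant then reaches genome-wide
#' significance (Z > 6) in the meta-analysed exposure GWAS, consistent
#' with the scenario's premise that the clustered variants are selected
#' instruments; per-variant sampling noise follows the standard GWAS
#' variance approximation se^2 = 1/(2 n f (1-f)) for a variance-1 trait.
#'
#' @param seed Integer seed; the full output is reproducible from it.
#' @param clusters Data.frame with columns n_snps, mean — the substantive
#'   ratio-effect clusters.
#' @param n_null,n_junk Null-mass and junk-outlier variant counts.
#' @param junk_range Range junk ratio effects are drawn from.
#' @param beta_exp_range Magnitude range of per-variant exposure effects.
#' @param eaf_range Allele-frequency range.
#' @param n_exp1,n_exp2 Exposure sub-study sample sizes (meta-analysed).
#' @param n_out Outcome GWAS sample size.
#' @param outcome_case_fraction Case fraction of the (binary-outcome)
#'   GWAS; outcome effects are log odds ratios and their sampling
#'   variance carries the binomial factor, se^2 = 1 / (2 n f (1-f) v)
#'   with v = phi (1 - phi). The default equals the cohort prevalence
#'   (a population-register disease GWAS); a case-enriched design can be
#'   emulated by raising it.
#' @param n_individuals Cohort size for individual-level simulation.
#' @param prevalence Target outcome prevalence in the cohort.
#' @param protein_fraction Fraction of the cohort carrying protein
#'   measurements (the molecular sub-sample; the remainder estimates the
#'   score-exposure association).
#' @param n_proteins Size of the protein panel.
#' @param architecture Data.frame with columns cluster (index into
#'   `clusters`), protein (index into the panel), beta_exp_protein
#'   (effect of the cluster-scaled exposure on the protein) and
#'   beta_protein_outcome (effect of the protein on outcome liability /
#'   log-odds). Empty by default (no true mediators).
#' @param protein_noise_sd Residual SD of protein levels.
#' @param n_protein_gwas Sample size of the protein GWAS (instrument
#'   discovery for the mediator -> outcome step).
#' @param n_instruments_per_protein Cis instruments simulated per protein.
#' @param step1_se,step2_se Sampling SEs used when mediation MR estimate
#'   tables are simulated directly at summary level.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    clusters = data.frame(n_snps = c(24, 73, 7), mean = c(0.98, -0.61, -1.74)),
    n_null = 360, n_junk = 0, junk_range = c(-5, 5),
    beta_exp_range = c(0.02, 0.08), eaf_range = c(0.1, 0.9),
    n_exp1 = 266130, n_exp2 = 322154, n_out = 247173,
    outcome_case_fraction = 0.085,
    n_individuals = 194682, prevalence = 0.085, protein_fraction = 0.107,
    n_proteins = 2922, architecture = NULL, protein_noise_sd = 1,
    n_protein_gwas = 54219, n_instruments_per_protein = 5L,
    step1_se = 0.03, step2_se = 0.05) {
  if (is.null(architecture))
    architecture <- data.frame(cluster = integer(), protein = integer(),
                               beta_exp_protein = numeric(),
                               beta_protein_outcome = numeric())
  stopifnot(all(clusters$n_snps >= 0), n_null >= 0, n_junk >= 0,
            prevalence > 0, prevalence < 1,
            protein_fraction > 0, protein_fraction < 1,
            all(architecture$cluster %in% seq_len(nrow(clusters))),
            all(architecture$protein %in% seq_len(n_proteins)))
  structure(list(
    seed = as.integer(seed), clusters = clusters, n_null = n_null,
    n_junk = n_junk, junk_range = junk_range,
    beta_exp_range = beta_exp_range, eaf_range = eaf_range,
    n_exp1 = n_exp1, n_exp2 = n_exp2, n_out = n_out,
    outcome_case_fraction = outcome_case_fraction,
    n_individuals = n_individuals, prevalence = prevalence,
    protein_fraction = protein_fraction, n_proteins = n_proteins,
    architecture = architecture, protein_noise_sd = protein_noise_sd,
    n_protein_gwas = n_protein_gwas,
    n_instruments_per_protein = as.integer(n_instruments_per_protein),
    step1_se = step1_se, step2_se = step2_se
  ), class = "simulation_config")
}

gwas_se <- function(n, eaf, var_factor = 1) {
  sqrt(1 / (2 * n * eaf * (1 - eaf) * var_factor))
}

observe_gwas <- function(truth, n, var_factor = 1) {
  se <- gwas_se(n, truth$eaf, var_factor)
  beta <- truth$beta_true + stats::rnorm(nrow(truth)) * se
  data.frame(
    rsid = truth$rsid, chr = truth$chr, pos = truth$pos,
    ea = truth$ea, oa = truth$oa, eaf = truth$eaf,
    beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)), n = n,
    stringsAsFactors = FALSE
  )
}

# variant scaffold shared by exposure and outcome tables
variant_scaffold <- function(n_snps, eaf_range) {
  chr <- as.character(rep_len(1:22, n_snps))
  pos <- unlist(lapply(1:22, function(c) {
    k <- sum(chr == c)
    if (k == 0) return(numeric(0))
    1e6 + (seq_len(k) - 1) * 2e6  # 2 Mb spacing: independent under 500 kb clumping
  }))
  ord <- order(as.integer(chr))
  pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), n_snps,
                                          replace = TRUE), , drop = FALSE]
  data.frame(
    rsid = sprintf("rs%05d", seq_len(n_snps)),
    chr = chr[ord], pos = pos,
    ea = pair[, 1], oa = pair[, 2],
    eaf = stats::runif(n_snps, eaf_range[1], eaf_range[2]),
    stringsAsFactors = FALSE
  )
}

#' Simulate exposure, outcome and protein GWAS summary statistics
#'
#' Draws per-variant true exposure effects, assigns each variant a true
#' ratio effect from its cluster (0 for the null mass, uniform over
#' `junk_range` for junk variants), sets the true outcome effect to
#' ratio x exposure effect, and observes every association with sampling
#' noise scaled by sample size and allele frequency. Two exposure
#' sub-study tables (for meta-analysis) and one outcome table are
#' returned; a fraction of outcome records have their allele pair swapped
#' or strand-complemented (resolvable at harmonisation) to exercise the
#' harmonisation step. Protein GWAS tables with cis instrument loci are
#' generated for every protein in the panel, wired through the mediation
#' architecture to the outcome.
#'
#' @param config A `simulation_config`.
#' @return List with `exposure1`, `exposure2`, `outcome` (canonical
#'   association tables), `truth` (rsid, cluster label, theta_true,
#'   beta_exp_true), `protein_gwas` (named list of per-protein lists:
#'   `assoc` for the protein, `outcome_assoc` for the same variants on
#'   the outcome, `locus`), `protein_truth` and the config.
#' @export
simulate_summary_stats <- function(config) {
  set.seed(config$seed)
  cl <- config$clusters
  n_subst <- sum(cl$n_snps)
  n_total <- n_subst + config$n_null + config$n_junk
  scaffold <- variant_scaffold(n_total, config$eaf_range)
  subst_lab <- if (nrow(cl) > 0)
    rep(paste0("cluster_", seq_len(nrow(cl))), cl$n_snps) else character(0)
  cluster_lab <- c(subst_lab, rep("null", config$n_null),
                   rep("junk", config$n_junk))
  theta <- c(rep(cl$mean, cl$n_snps), rep(0, config$n_null),
             stats::runif(config$n_junk, config$junk_range[1], config$junk_range[2]))
  # shuffle variant-to-cluster attachment so clusters are not positional
  perm <- sample.int(n_total)
  cluster_lab <- cluster_lab[perm]
  theta <- theta[perm]
  beta_exp <- stats::runif(n_total, config$beta_exp_range[1],
                           config$beta_exp_range[2]) *
    sample(c(-1, 1), n_total, replace = TRUE)
  truth_exp <- cbind(scaffold, beta_true = beta_exp)
  truth_out <- cbind(scaffold, beta_true = theta * beta_exp)
  exposure1 <- observe_gwas(truth_exp, config$n_exp1)
  exposure2 <- observe_gwas(truth_exp, config$n_exp2)
  v_out <- config$outcome_case_fraction * (1 - config$outcome_case_fraction)
  outcome <- observe_gwas(truth_out, config$n_out, var_factor = v_out)
  # re-express some outcome records on the swapped / complemented allele
  swap <- stats::runif(n_total) < 0.3
  outcome$beta[swap] <- -outcome$beta[swap]
  outcome$eaf[swap] <- 1 - outcome$eaf[swap]
  tmp <- outcome$ea[swap]; outcome$ea[swap] <- outcome$oa[swap]
  outcome$oa[swap] <- tmp
  flip_strand <- stats::runif(n_total) < 0.3
  outcome$ea[flip_strand] <- unname(ALLELE_COMPLEMENT[outcome$ea[flip_strand]])
  outcome$oa[flip_strand] <- unname(ALLELE_COMPLEMENT[outcome$oa[flip_strand]])

  protein <- simulate_protein_gwas(config)
  list(
    exposure1 = exposure1, exposure2 = exposure2, outcome = outcome,
    truth = data.frame(rsid = scaffold$rsid, cluster = cluster_lab,
                       theta_true = theta, beta_exp_true = beta_exp,
                       stringsAsFactors = FALSE),
    protein_gwas = protein$gwas, protein_truth = protein$truth,
    config = config
  )
}

# cis-instrumented protein GWAS tables wired to the outcome through the
# mediation architecture; only proteins appearing in the architecture plus
# a seed-stable sample of null proteins get tables (the panel itself can
# be large; callers screening the full panel use
# simulate_mediation_tables()).
simulate_protein_gwas <- function(config, max_null_proteins = 25L) {
  arch <- config$architecture
  prot_effect <- rep(0, config$n_proteins)
  if (nrow(arch) > 0)
    prot_effect[arch$protein] <- arch$beta_protein_outcome
  with_tables <- sort(unique(c(
    arch$protein,
    utils::head(setdiff(seq_len(config$n_proteins), arch$protein),
                max_null_proteins)
  )))
  gwas <- list()
  truth <- list()
  m <- config$n_instruments_per_protein
  for (pi_ in with_tables) {
    chrom <- as.character(sample.int(22, 1))
    start <- round(stats::runif(1, 5e6, 1e8))
    locus <- list(chrom = chrom, start = start, end = start + 5e4)
    pos <- start + round(stats::runif(m, -8e5, 8e5))
    pair <- NONPALINDROMIC_PAIRS[sample.int(nrow(NONPALINDROMIC_PAIRS), m,
                                            replace = TRUE), , drop = FALSE]
    eaf <- stats::runif(m, config$eaf_range[1], config$eaf_range[2])
    b_prot <- stats::runif(m, 0.1, 0.5) * sample(c(-1, 1), m, replace = TRUE)
    scaffold <- data.frame(
      rsid = sprintf("P%04d_snp%02d", pi_, seq_len(m)),
      chr = chrom, pos = pos, ea = pair[, 1], oa = pair[, 2], eaf = eaf,
      stringsAsFactors = FALSE
    )
    v_out <- config$outcome_case_fraction * (1 - config$outcome_case_fraction)
    assoc <- observe_gwas(cbind(scaffold, beta_true = b_prot),
                          config$n_protein_gwas)
    out_assoc <- observe_gwas(cbind(scaffold,
                                    beta_true = prot_effect[pi_] * b_prot),
                              config$n_out, var_factor = v_out)
    key <- paste0("protein_", pi_)
    # LD-free block: identity r-squared matrix over the locus instruments
    ld <- diag(m)
    dimnames(ld) <- list(scaffold$rsid, scaffold$rsid)
    gwas[[key]] <- list(assoc = assoc, outcome_assoc = out_assoc,
                        locus = locus, ld = ld)
    truth[[key]] <- data.frame(protein = key, effect_on_outcome = prot_effect[pi_],
                               stringsAsFactors = FALSE)
  }
  list(gwas = gwas, truth = do.call(rbind, truth))
}

#' Simulate mediation MR estimate tables at summary level
#'
#' Directly draws the step-1 (cluster-scaled exposure -> protein) and
#' step-2 (protein -> outcome) MR estimate tables for the full panel:
#' every (cluster, protein) step-1 estimate and every step-2 estimate is
#' its architecture-implied true value (0 off-architecture) plus Normal
#' sampling noise with the configured SEs. This is the desk-scale route
#' for calibrating the double-FDR screen on a panel-sized family.
#'
#' @param config A `simulation_config`.
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `step1`, `step2` (estimate tables) and `truth`
#'   (logical matrix of true mediations, clusters x proteins).
#' @export
simulate_mediation_tables <- function(config, seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  K <- nrow(config$clusters)
  P <- config$n_proteins
  arch <- config$architecture
  true1 <- matrix(0, K, P)
  true2 <- rep(0, P)
  if (nrow(arch) > 0) {
    true1[cbind(arch$cluster, arch$protein)] <- arch$beta_exp_protein
    true2[arch$protein] <- arch$beta_protein_outcome
  }
  prot <- sprintf("protein_%d", seq_len(P))
  step1 <- data.frame(
    cluster = rep(paste0("cluster_", seq_len(K)), each = P),
    protein = rep(prot, K),
    beta = as.vector(t(true1)) + stats::rnorm(K * P) * config$step1_se,
    se = config$step1_se, stringsAsFactors = FALSE
  )
  step1$p <- 2 * stats::pnorm(-abs(step1$beta / step1$se))
  step2 <- data.frame(
    protein = prot,
    beta = true2 + stats::rnorm(P) * config$step2_se,
    se = config$step2_se, stringsAsFactors = FALSE
  )
  step2$p <- 2 * stats::pnorm(-abs(step2$beta / step2$se))
  truth <- true1 != 0 & matrix(rep(true2 != 0, each = K), K, P)
  rownames(truth) <- paste0("cluster_", seq_len(K))
  colnames(truth) <- prot
  list(step1 = step1, step2 = step2, truth = truth)
}

#' Simulate an individual-level cohort with genotypes, proteins, outcome
#'
#' Genotypes are Binomial(2, f) dosages for the same variant scaffold as
#' the summary statistics; the quantitative exposure is the genetic score
#' plus Normal noise filled to unit variance; panel proteins are linear
#' in the cluster-specific genetic exposure components per the mediation
#' architecture plus Normal noise; the binary outcome is Bernoulli on a
#' logistic liability combining the cluster-specific ratio effects and
#' the protein effects, with the intercept tuned by bisection to the
#' target prevalence. Two disjoint sub-samples are flagged: the molecular
#' sub-sample (protein measurements) and its complement (score-exposure
#' estimation), enabling the two-sample split within one cohort.
#'
#' @param config A `simulation_config`.
#' @param truth Optional `truth` table from [simulate_summary_stats()]
#'   run on the same config (regenerated if omitted) — fixes the variant
#'   scaffold, cluster attachment and true exposure effects.
#' @return List with `genotypes` (dosages + scored_allele), `cohort`
#'   (data.frame id, exposure, case, subsample) , `proteins` (matrix,
#'   molecular sub-sample rows only are measured, others NA), `truth`,
#'   and the achieved prevalence.
#' @export
simulate_cohort <- function(config, truth = NULL) {
  if (is.null(truth)) {
    ss <- simulate_summary_stats(config)
    truth <- merge(ss$truth,
                   ss$exposure1[, c("rsid", "ea", "oa", "eaf")], by = "rsid",
                   sort = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- config$n_individuals
  m <- nrow(truth)
  D <- matrix(stats::rbinom(n * m, 2, rep(truth$eaf, each = n)), n, m)
  colnames(D) <- truth$rsid
  rownames(D) <- sprintf("id%06d", seq_len(n))
  g_score <- as.vector(D %*% truth$beta_exp_true)
  g_var <- stats::var(g_score)
  resid_sd <- sqrt(max(1 - g_var, 0.05))
  exposure <- g_score + stats::rnorm(n, 0, resid_sd)
  # cluster-specific genetic exposure components
  clusters <- sort(unique(truth$cluster[grepl("^cluster_", truth$cluster)]))
  comp <- sapply(clusters, function(cl) {
    j <- truth$cluster == cl
    as.vector(D[, j, drop = FALSE] %*% truth$beta_exp_true[j])
  })
  if (length(clusters) == 1) comp <- matrix(comp, ncol = 1)
  colnames(comp) <- clusters
  # proteins
  arch <- config$architecture
  P <- config$n_proteins
  prot <- matrix(stats::rnorm(n * P, 0, config$protein_noise_sd), n, P)
  colnames(prot) <- sprintf("protein_%d", seq_len(P))
  if (nrow(arch) > 0) {
    for (i in seq_len(nrow(arch))) {
      prot[, arch$protein[i]] <- prot[, arch$protein[i]] +
        arch$beta_exp_protein[i] * comp[, arch$cluster[i]]
    }
  }
  # liability: cluster ratio effects act through their components, plus
  # direct protein effects
  eta <- as.vector(comp %*% config$clusters$mean)
  if (nrow(arch) > 0) {
    for (i in seq_len(nrow(arch)))
      eta <- eta + arch$beta_protein_outcome[i] * prot[, arch$protein[i]]
  }
  alpha <- prevalence_intercept(eta, config$prevalence)
  case <- stats::rbinom(n, 1, stats::plogis(alpha + eta))
  # two-sample split
  n_mol <- round(config$protein_fraction * n)
  mol <- sample.int(n, n_mol)
  subsample <- rep("score", n)
  subsample[mol] <- "molecular"
  prot[subsample != "molecular", ] <- NA_real_
  cohort <- data.frame(
    id = rownames(D), exposure = exposure, case = case,
    subsample = subsample, stringsAsFactors = FALSE
  )
  list(
    genotypes = list(dosages = D,
                     scored_allele = stats::setNames(truth$ea, truth$rsid)),
    cohort = cohort, proteins = prot, truth = truth,
    prevalence = mean(case), intercept = alpha
  )
}

# solve E[plogis(alpha + eta)] = target by bisection
prevalence_intercept <- function(eta, target, tol = 1e-6) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -30; hi <- 30
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
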