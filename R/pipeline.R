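# End-to-end drivers: part 1 (meta-analysis -> clumping -> harmonisation
# -> Steiger -> clustering -> per-cluster IVW) and part 2 (two-step
# mediation through a molecular panel), with structured per-stage
# bookkeeping and a JSON run report.

#' Default analysis parameters
#'
#' One place for every threshold the pipeline applies: clumping window
#' 500 kb at r-squared 0.001, instrument p < 5e-8, palindromic ambiguity
#' band starting at eaf 0.42, Steiger alpha 0.05, mixture model selection
#' up to K_max = 5 with 30 restarts, assignment probability threshold 0.8
#' and minimum cluster size 4, FDR 0.05 for both mediation steps, protein
#' instrument p < 1.7e-11 with >= 3 independent variants of which >= 1
#' cis (window 1 Mb), and 1e6 Monte Carlo draws.
#'
#' @param ... Overrides for any default.
#' @return Named list of parameters.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    window_kb = 500, r2_threshold = 0.001, p_threshold = 5e-8,
    maf_ambiguity_threshold = 0.42, steiger_alpha = 0.05,
    K_max = 5L, n_restarts = 30L, seed = 1L,
    prob_threshold = 0.8, min_cluster_size = 4L,
    second_order_wald = TRUE,
    fdr_alpha = 0.05, pooled_step1_fdr = FALSE,
    protein_p_threshold = 1.7e-11, min_snps = 3L, min_cis = 1L,
    cis_window_kb = 1000,
    mc_draws = 1e6, mc_level = 0.95,
    output_dir = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

stage_count <- function(log, stage, n_in, n_out) {
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        stringsAsFactors = FALSE))
}

#' Part 1: variant clustering and per-cluster MR
#'
#' Runs the full first-stage analysis: optional fixed-effect
#' meta-analysis of two exposure tables, clumping to independent
#' genome-wide-significant instruments, harmonisation against the
#' outcome, Steiger directionality filtering, ratio-mixture clustering
#' with BIC model selection, per-variant assignment and per-cluster IVW
#' MR. Every filter's in/out counts are recorded.
#'
#' @param exposure Canonical exposure association table (or sub-study 1).
#' @param outcome Canonical outcome association table.
#' @param exposure2 Optional second exposure sub-study, meta-analysed
#'   with the first.
#' @param ld Optional LD matrix for clumping.
#' @param config Parameter list from [default_run_config()].
#' @return List of class `part1_result`: `model` (selected
#'   `mixture_model`), `assignment`, `cluster_mr` (per-cluster table:
#'   n_snps, cluster_mean, IVW beta with 95% CI), `pairs` (post-filter
#'   harmonised pairs), `ratios`, `stage_log`, `exclusions`, `config`.
#' @export
run_part1 <- function(exposure, outcome, exposure2 = NULL, ld = NULL,
                      config = default_run_config()) {
  log <- data.frame(stage = character(), n_in = integer(), n_out = integer())
  exclusions <- list()
  exp_stats <- if (!is.null(exposure2)) {
    m <- fixed_effect_meta(exposure, exposure2)
    log <- stage_count(log, "meta", nrow(exposure) + nrow(exposure2), nrow(m))
    m
  } else exposure
  kept <- clump(exp_stats, ld = ld, window_kb = config$window_kb,
                r2_threshold = config$r2_threshold,
                p_threshold = config$p_threshold)
  log <- stage_count(log, "clump", nrow(exp_stats), length(kept))
  exp_sel <- exp_stats[match(kept, exp_stats$rsid), , drop = FALSE]
  h <- harmonise(exp_sel, outcome,
                 maf_ambiguity_threshold = config$maf_ambiguity_threshold)
  exclusions$harmonise <- h$exclusions
  log <- stage_count(log, "harmonise", nrow(exp_sel), nrow(h$pairs))
  st <- steiger_filter(h$pairs, alpha = config$steiger_alpha)
  exclusions$steiger <- st$exclusions
  log <- stage_count(log, "steiger", nrow(h$pairs), nrow(st$pairs))
  pairs <- st$pairs
  ratios <- wald_ratio(pairs, second_order = config$second_order_wald)
  model <- select_model(ratios, K_max = config$K_max,
                        n_restarts = config$n_restarts, seed = config$seed)
  assignment <- assign_clusters(model, ratios,
                                prob_threshold = config$prob_threshold,
                                min_cluster_size = config$min_cluster_size)
  cluster_mr <- cluster_ivw(assignment, pairs,
                            second_order = config$second_order_wald)
  log <- stage_count(log, "cluster", nrow(ratios),
                     sum(assignment$assignments$confident))
  res <- structure(list(
    model = model, assignment = assignment, cluster_mr = cluster_mr,
    pairs = pairs, ratios = ratios, stage_log = log,
    exclusions = exclusions, config = config
  ), class = "part1_result")
  if (!is.null(config$output_dir)) write_part1_outputs(res, config$output_dir)
  res
}

#' @export
print.part1_result <- function(x, ...) {
  cat("Part 1: ratio clustering and per-cluster MR\n")
  cat(sprintf("  selected K = %d (BIC)\n", x$model$K))
  print(x$stage_log, row.names = FALSE)
  print(x$cluster_mr, row.names = FALSE)
  invisible(x)
}

write_part1_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$assignment$assignments,
                     file.path(dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$cluster_mr, file.path(dir, "cluster_mr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  card <- list(K = res$model$K, means = res$model$means,
               pi = as.list(res$model$pi), bic = res$model$bic,
               log_likelihood = res$model$log_likelihood,
               seed = res$model$seed,
               n_restarts = res$model$n_restarts,
               config = res$config[setdiff(names(res$config), "output_dir")],
               stage_log = res$stage_log)
  jsonlite::write_json(card, file.path(dir, "model_card.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# step-1 mediation MR on the cohort: per (cluster, protein) Wald ratios
# of cluster-score effects, with the disjoint-sample discipline asserted
mediation_step1 <- function(part1, cohort_data, covariates = NULL) {
  assignments <- part1$assignment$assignments
  truth_cols <- cohort_data$genotypes
  cohort <- cohort_data$cohort
  proteins <- cohort_data$proteins
  mol <- cohort$subsample == "molecular"
  assert_disjoint_samples(cohort$id[mol], cohort$id[!mol])
  clusters <- setdiff(unique(assignments$label[assignments$confident]),
                      c("null", "junk"))
  prot_names <- colnames(proteins)
  rows <- list()
  den_by_cluster <- list()
  for (cl in sort(clusters)) {
    ids <- assignments$rsid[assignments$confident & assignments$label == cl]
    w <- part1$pairs[match(ids, part1$pairs$rsid), c("rsid", "ea", "beta_exp")]
    weights <- data.frame(rsid = w$rsid, allele = w$ea, weight = w$beta_exp,
                          stringsAsFactors = FALSE)
    score <- compute_pgs(truth_cols, weights)
    cov_score <- if (is.null(covariates)) NULL else covariates[!mol, , drop = FALSE]
    cov_mol <- if (is.null(covariates)) NULL else covariates[mol, , drop = FALSE]
    den <- linear_association(score[!mol],
                              inverse_normal_transform(cohort$exposure[!mol]),
                              cov_score)
    den_by_cluster[[cl]] <- den
    for (pn in prot_names) {
      num <- linear_association(score[mol], proteins[mol, pn], cov_mol)
      wmr <- one_sample_wald(num, den)
      rows[[paste(cl, pn)]] <- data.frame(
        cluster = cl, protein = pn, beta = wmr$wald, se = wmr$se, p = wmr$p,
        stringsAsFactors = FALSE
      )
    }
  }
  list(step1 = do.call(rbind, rows), den = den_by_cluster)
}

# step-2 mediation MR from protein GWAS summary statistics: instrument
# selection, harmonisation to the outcome, IVW + pleiotropy/heterogeneity
# diagnostics
mediation_step2 <- function(protein_gwas, config, ld = NULL) {
  rows <- list()
  details <- list()
  for (pn in names(protein_gwas)) {
    pg <- protein_gwas[[pn]]
    sel <- select_instruments(pg$assoc, pg$locus,
                              ld = if (!is.null(pg$ld)) pg$ld else ld,
                              p_threshold = config$protein_p_threshold,
                              cis_window_kb = config$cis_window_kb,
                              window_kb = config$window_kb,
                              r2_threshold = config$r2_threshold,
                              min_snps = config$min_snps,
                              min_cis = config$min_cis)
    details[[pn]] <- sel
    if (!sel$eligible) next
    h <- harmonise(sel$instruments, pg$outcome_assoc,
                   maf_ambiguity_threshold = config$maf_ambiguity_threshold)
    if (nrow(h$pairs) < config$min_snps) next
    ratios <- wald_ratio(h$pairs, second_order = config$second_order_wald)
    est <- ivw(ratios)
    egger <- egger_intercept_test(h$pairs)
    rows[[pn]] <- data.frame(
      protein = pn, beta = est$beta, se = est$se, p = est$p,
      n_snps = est$n_snps, Q = est$Q, Q_p = est$Q_p,
      egger_intercept = egger$intercept,
      egger_intercept_p = egger$intercept_p,
      stringsAsFactors = FALSE
    )
  }
  list(step2 = do.call(rbind, rows), instruments = details)
}

#' Part 2: two-step mediation MR through a molecular panel
#'
#' Step 1 estimates the cluster-scaled exposure effect on every panel
#' protein by one-sample Wald MR with cluster-specific allele scores,
#' using the cohort's two disjoint sub-samples (score-exposure in one,
#' score-protein in the other; disjointness is asserted). Step 2
#' estimates each eligible protein's effect on the outcome by IVW MR over
#' its selected instruments, with MR-Egger intercept and Cochran's Q
#' diagnostics. Candidates passing the double FDR screen receive
#' product-of-coefficients mediation estimates with delta-method SEs and
#' Monte Carlo CIs, signed proportions mediated against the cluster
#' totals from part 1, and all pairwise between-cluster contrasts.
#'
#' Either the cohort route (via `cohort_data`) or precomputed `step1` /
#' `step2` estimate tables can be supplied.
#'
#' @param part1 A `part1_result` (for cluster weights and total effects).
#' @param cohort_data List from [simulate_cohort()] (or same shape):
#'   genotypes, cohort, proteins.
#' @param protein_gwas Named per-protein list of `assoc`,
#'   `outcome_assoc`, `locus` (see [simulate_summary_stats()]).
#' @param step1,step2 Optional precomputed estimate tables replacing the
#'   cohort / protein-GWAS routes.
#' @param covariates Optional covariate matrix for the step-1 models.
#' @param ld Optional LD matrix for protein instrument clumping.
#' @param config Parameter list from [default_run_config()].
#' @return List of class `part2_result`: `candidates`, `mediation`
#'   (per-candidate results), `contrasts`, `step1`, `step2`,
#'   `instrument_log`, `config`.
#' @export
run_part2 <- function(part1, cohort_data = NULL, protein_gwas = NULL,
                      step1 = NULL, step2 = NULL, covariates = NULL,
                      ld = NULL, config = default_run_config()) {
  instrument_log <- NULL
  if (is.null(step1)) {
    if (is.null(cohort_data))
      stop("either step1 or cohort_data must be supplied")
    step1 <- mediation_step1(part1, cohort_data, covariates)$step1
  }
  if (is.null(step2)) {
    if (is.null(protein_gwas))
      stop("either step2 or protein_gwas must be supplied")
    s2 <- mediation_step2(protein_gwas, config, ld = ld)
    step2 <- s2$step2
    instrument_log <- s2$instruments
  }
  if (is.null(step2) || nrow(step2) == 0) {
    empty <- data.frame(cluster = character(), protein = character(),
                        beta1 = numeric(), se1 = numeric(), q1 = numeric(),
                        beta2 = numeric(), se2 = numeric(), q2 = numeric(),
                        stringsAsFactors = FALSE)
    scr <- list(candidates = empty, step1 = step1, step2 = step2,
                excluded = unique(step1$protein))
  } else {
    scr <- screen_mediators(step1, step2, alpha = config$fdr_alpha,
                            pooled_step1 = config$pooled_step1_fdr)
  }
  totals <- part1$cluster_mr[, c("cluster", "beta")]
  med <- mediation_results(scr$candidates, totals,
                           draws = config$mc_draws, seed = config$seed,
                           level = config$mc_level)
  # contrasts compare every cluster's step-1 effect on a candidate
  # protein (the step-2 estimate is shared), not just candidate pairs
  cand_prot <- unique(scr$candidates$protein)
  ci <- scr$step1[scr$step1$protein %in% cand_prot, , drop = FALSE]
  j <- match(ci$protein, scr$step2$protein)
  contrast_input <- data.frame(
    cluster = ci$cluster, protein = ci$protein,
    beta1 = ci$beta, se1 = ci$se, q1 = ci$q,
    beta2 = scr$step2$beta[j], se2 = scr$step2$se[j], q2 = scr$step2$q[j],
    stringsAsFactors = FALSE
  )
  contr <- cluster_contrasts(contrast_input, draws = config$mc_draws,
                             seed = config$seed, level = config$mc_level)
  res <- structure(list(
    candidates = scr$candidates, mediation = med, contrasts = contr,
    step1 = scr$step1, step2 = scr$step2,
    instrument_log = instrument_log, config = config
  ), class = "part2_result")
  if (!is.null(config$output_dir)) write_part2_outputs(res, config$output_dir)
  res
}

#' @export
print.part2_result <- function(x, ...) {
  cat("Part 2: two-step mediation MR\n")
  cat(sprintf("  %d candidate (cluster, protein) pair(s) after double FDR\n",
              nrow(x$candidates)))
  if (nrow(x$mediation) > 0) {
    show <- x$mediation[, c("cluster", "protein", "mediated", "se_mediated",
                            "ci_lower", "ci_upper", "proportion", "tier")]
    print(show, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

write_part2_outputs <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("candidates", "mediation", "contrasts", "step1", "step2")) {
    tb <- res[[nm]]
    if (!is.null(tb) && nrow(tb) > 0)
      utils::write.table(tb, file.path(dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- list(
    n_candidates = nrow(res$candidates),
    seed = res$config$seed, mc_draws = res$config$mc_draws,
    config = res$config[setdiff(names(res$config), "output_dir")]
  )
  jsonlite::write_json(report, file.path(dir, "mediation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
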