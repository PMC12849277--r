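# Weighted allele scores on individual-level data and one-sample
# Wald-ratio MR.
#
# A genotype matrix is individuals x variants with dosages in [0, 2] and a
# per-variant scored allele; weights come from an external GWAS (here, the
# exposure meta-analysis) as (rsid, allele, weight).

#' Rank-based inverse normal transform
#'
#' Maps the value with rank r (average ranks for ties) to
#' qnorm((r - offset) / (n - 2 offset + 1)); the default offset 3/8 is the
#' Blom constant. Missing values are excluded from ranking and stay
#' missing.
#'
#' @param values Numeric vector.
#' @param offset Rank offset (default 3/8).
#' @return Transformed vector, same length and order.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  obs <- !is.na(values)
  x <- values[obs]
  if (length(x) < 2) stop("need at least 2 non-missing values")
  if (length(unique(x)) == 1) stop("degenerate ranks: all values identical")
  r <- rank(x, ties.method = "average")
  out <- values
  out[obs] <- stats::qnorm((r - offset) / (length(x) - 2 * offset + 1))
  out
}

#' Per-individual weighted allele score
#'
#' score_i = sum_j weight_j * dosage_ij over the variants carrying a
#' weight. A weight whose allele does not match the variant's scored
#' allele is applied to the opposite allele's dosage (sign flip with
#' dosage -> 2 - dosage), which leaves scores invariant to the allele a
#' weight is expressed on. Weighted variants absent from the matrix are
#' ignored with a message; zero overlap is an error.
#'
#' @param genotypes List with `dosages` (individuals x variants matrix,
#'   variant rsids as colnames) and `scored_allele` (named character
#'   vector, per variant).
#' @param weights Data.frame with columns rsid, allele, weight.
#' @return Named numeric vector of scores (individual ids from rownames).
#' @export
compute_pgs <- function(genotypes, weights) {
  D <- genotypes$dosages
  hit <- weights$rsid %in% colnames(D)
  if (!any(hit)) stop("no weighted variants present in the genotype matrix")
  if (any(!hit))
    message("compute_pgs: ", sum(!hit), " weighted variant(s) not genotyped; ignored")
  w <- weights[hit, , drop = FALSE]
  scored <- genotypes$scored_allele[w$rsid]
  flip <- w$allele != scored
  wv <- ifelse(flip, -w$weight, w$weight)
  base <- sum(2 * w$weight[flip])  # 2 - dosage contribution of flipped variants
  as.vector(D[, w$rsid, drop = FALSE] %*% wv) + base
}

assert_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
}

build_design <- function(score, covariates) {
  X <- cbind(`(Intercept)` = 1, score = score)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(covariates)
    if (is.null(colnames(cv))) colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  X
}

#' Linear association of an allele score with a quantitative trait
#'
#' Ordinary least squares of the trait on the score with an intercept and
#' the supplied covariate columns; returns the score coefficient.
#'
#' @param score Per-individual score.
#' @param outcome Quantitative trait.
#' @param covariates Optional numeric matrix/data.frame of covariate
#'   columns (already coded; factors must be pre-expanded).
#' @return List with beta, se, p (for the score term) and n.
#' @export
linear_association <- function(score, outcome, covariates = NULL) {
  X <- build_design(score, covariates)
  keep <- stats::complete.cases(X, outcome)
  X <- X[keep, , drop = FALSE]
  y <- outcome[keep]
  if (nrow(X) <= ncol(X) + 1) stop("too few observations for the design")
  assert_full_rank(X)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- nrow(X) - ncol(X)
  sigma2 <- rss / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- unname(fit$coefficients["score"])
  list(beta = beta, se = se,
       p = 2 * stats::pt(-abs(beta / se), df), n = nrow(X))
}

#' Logistic association of an allele score with a binary outcome
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`, relative
#' log-likelihood convergence 1e-10) of case status on the score plus
#' covariates; the score coefficient is a log odds ratio with its SE from
#' the observed information.
#'
#' @param score Per-individual score.
#' @param case Binary outcome in \{0, 1\}.
#' @param covariates Optional covariate columns.
#' @return List with log_or, se, p, n.
#' @export
logistic_association <- function(score, case, covariates = NULL) {
  if (!all(case %in% c(0, 1))) stop("case must be coded 0/1")
  if (length(unique(case)) < 2) stop("both outcome classes must be present")
  X <- build_design(score, covariates)
  keep <- stats::complete.cases(X, case)
  X <- X[keep, , drop = FALSE]
  y <- case[keep]
  if (nrow(X) <= ncol(X) + 1) stop("too few observations for the design")
  assert_full_rank(X)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (separation && max(abs(fit$coefficients)) > 15)
    stop("perfect separation: fitted probabilities reached 0/1 and ",
         "coefficients diverged")
  if (!fit$converged) stop("logistic fit did not converge")
  # observed-information SEs
  p_hat <- fit$fitted.values
  W <- p_hat * (1 - p_hat)
  info <- crossprod(X * sqrt(W))
  se <- sqrt(chol2inv(chol(info))[2, 2])
  log_or <- unname(fit$coefficients["score"])
  list(log_or = log_or, se = se,
       p = 2 * stats::pnorm(-abs(log_or / se)), n = nrow(X))
}

#' One-sample Wald-ratio MR estimate
#'
#' wald = beta_num / beta_den with first-order SE |se_num / beta_den|,
#' where the numerator is the score-outcome association (log-OR or trait
#' units) and the denominator the score-exposure association.
#'
#' @param num List with `beta` (or `log_or`) and `se` — the score-outcome
#'   association.
#' @param den List with `beta` and `se` — the score-exposure association.
#' @return List with wald, se, ci_lower, ci_upper, p and the inputs.
#' @export
one_sample_wald <- function(num, den) {
  bn <- if (!is.null(num$beta)) num$beta else num$log_or
  bd <- den$beta
  if (bd == 0) stop("undefined ratio: score-exposure beta is 0")
  wald <- bn / bd
  se <- abs(num$se / bd)
  z <- stats::qnorm(0.975)
  list(wald = wald, se = se,
       ci_lower = wald - z * se, ci_upper = wald + z * se,
       p = 2 * stats::pnorm(-abs(wald / se)),
       beta_num = bn, se_num = num$se, beta_den = bd, se_den = den$se)
}

#' Assert two individual-id sets are disjoint
#'
#' The two-sample split within one cohort requires that the individuals
#' providing the score-exposure estimate share no ids with those
#' providing the molecular measurements; drivers call this before any
#' mediation step-1 estimate is formed.
#'
#' @param ids_a,ids_b Character/integer id vectors.
#' @return Invisibly TRUE; error on overlap.
#' @export
assert_disjoint_samples <- function(ids_a, ids_b) {
  ov <- intersect(ids_a, ids_b)
  if (length(ov) > 0)
    stop("sub-samples overlap (", length(ov),
         " shared individuals); the two-sample split requires disjoint sets")
  invisible(TRUE)
}
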