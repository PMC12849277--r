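# Core two-sample MR estimators and diagnostics.
#
# Ratio estimates are plain data.frames with columns rsid, theta, se_theta
# (and implicitly weight 1/se_theta^2); MR estimates are one-row
# data.frames of class "mr_estimate".

mr_estimate <- function(method, beta, se, n_snps,
                        Q = NA_real_, Q_df = NA_real_, Q_p = NA_real_,
                        egger_intercept = NA_real_, egger_intercept_p = NA_real_) {
  stopifnot(se > 0, n_snps >= 1)
  z <- beta / se
  out <- data.frame(
    method = method, beta = beta, se = se,
    ci_lower = beta - stats::qnorm(0.975) * se,
    ci_upper = beta + stats::qnorm(0.975) * se,
    p = 2 * stats::pnorm(-abs(z)),
    n_snps = n_snps, Q = Q, Q_df = Q_df, Q_p = Q_p,
    egger_intercept = egger_intercept, egger_intercept_p = egger_intercept_p,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Fixed-effect inverse-variance meta-analysis of two association tables
#'
#' Combines two summary-statistic tables for the same trait, variant by
#' variant, with fixed-effect inverse-variance weights:
#' beta = (b_a/se_a^2 + b_b/se_b^2) / (1/se_a^2 + 1/se_b^2) and
#' se = (1/se_a^2 + 1/se_b^2)^(-1/2). Sample sizes add; the p-value comes
#' from the normal Z. Both tables must already share allele orientation
#' per rsid (harmonise study B to study A first if needed); an allele
#' mismatch is a hard error.
#'
#' Variants present in only one table are passed through unchanged.
#'
#' @param a,b Canonical association data.frames for the same trait.
#' @return A canonical association data.frame of the meta-analysed
#'   variants.
#' @export
fixed_effect_meta <- function(a, b) {
  shared <- intersect(a$rsid, b$rsid)
  ai <- match(shared, a$rsid)
  bi <- match(shared, b$rsid)
  if (length(shared) > 0) {
    mism <- a$ea[ai] != b$ea[bi] | a$oa[ai] != b$oa[bi]
    if (any(mism))
      stop("allele mismatch in meta-analysis for: ",
           paste(utils::head(shared[mism], 5), collapse = ", "))
  }
  wa <- 1 / a$se[ai]^2
  wb <- 1 / b$se[bi]^2
  beta <- (a$beta[ai] * wa + b$beta[bi] * wb) / (wa + wb)
  se <- 1 / sqrt(wa + wb)
  n <- a$n[ai] + b$n[bi]
  eaf <- ifelse(is.na(a$eaf[ai]) | is.na(b$eaf[bi]), NA_real_,
                (a$eaf[ai] * a$n[ai] + b$eaf[bi] * b$n[bi]) / n)
  meta <- data.frame(
    rsid = shared, chr = a$chr[ai], pos = a$pos[ai],
    ea = a$ea[ai], oa = a$oa[ai], eaf = eaf,
    beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)), n = n,
    stringsAsFactors = FALSE
  )
  only_a <- a[!a$rsid %in% shared, intersect(CANONICAL_COLS, names(a)), drop = FALSE]
  only_b <- b[!b$rsid %in% shared, intersect(CANONICAL_COLS, names(b)), drop = FALSE]
  out <- rbind(meta, only_a, only_b)
  rownames(out) <- NULL
  out
}

#' Per-variant Wald ratio estimates
#'
#' theta = beta_out / beta_exp with the first-order delta-method standard
#' error |se_out / beta_exp| (the exposure uncertainty is ignored, the
#' usual convention for strong instruments). A second-order SE that also
#' carries se_exp, sqrt(se_out^2/beta_exp^2 +
#' beta_out^2 se_exp^2 / beta_exp^4), is available behind `second_order`.
#'
#' @param pairs Harmonised pair data.frame (or any data.frame with
#'   rsid, beta_exp, se_exp, beta_out, se_out).
#' @param second_order Use the second-order delta SE (default FALSE).
#' @return Data.frame with columns rsid, theta, se_theta, weight.
#' @export
wald_ratio <- function(pairs, second_order = FALSE) {
  if (any(pairs$beta_exp == 0)) stop("undefined ratio: beta_exp = 0")
  theta <- pairs$beta_out / pairs$beta_exp
  se <- if (second_order) {
    sqrt(pairs$se_out^2 / pairs$beta_exp^2 +
           pairs$beta_out^2 * pairs$se_exp^2 / pairs$beta_exp^4)
  } else {
    abs(pairs$se_out / pairs$beta_exp)
  }
  data.frame(rsid = pairs$rsid, theta = theta, se_theta = se,
             weight = 1 / se^2, stringsAsFactors = FALSE)
}

#' Inverse-variance weighted MR estimate
#'
#' Fixed-effect IVW over per-variant Wald ratios: beta = sum(w theta) /
#' sum(w), se = sum(w)^(-1/2) with w = 1/se_theta^2. The multiplicative
#' random-effect variance rescaling is applied only when
#' `random_effects = TRUE` (the residual scale is then floored at 1, and
#' only inflates the SE).
#'
#' @param estimates Ratio-estimate data.frame from [wald_ratio()].
#' @param random_effects Apply the multiplicative random-effects variance
#'   (default FALSE).
#' @return An `mr_estimate` one-row data.frame (heterogeneity fields are
#'   filled when at least two variants are supplied).
#' @export
ivw <- function(estimates, random_effects = FALSE) {
  if (nrow(estimates) == 0) stop("ivw requires at least one ratio estimate")
  w <- 1 / estimates$se_theta^2
  beta <- sum(w * estimates$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- Q_df <- Q_p <- NA_real_
  if (nrow(estimates) >= 2) {
    qres <- cochran_q(estimates, beta)
    Q <- qres$Q; Q_df <- qres$df; Q_p <- qres$p
    if (random_effects) {
      phi <- max(1, Q / Q_df)
      se <- se * sqrt(phi)
    }
  }
  mr_estimate("ivw", beta, se, nrow(estimates), Q = Q, Q_df = Q_df, Q_p = Q_p)
}

#' MR-Egger intercept test
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with a free intercept and weights 1/se_out^2, after
#' orienting every variant so beta_exp > 0 (pair sign flips). A non-zero
#' intercept indicates directional pleiotropy. Standard errors are the
#' fixed-effect form (X'WX)^(-1), matching the package-wide fixed-effect
#' convention.
#'
#' @param pairs Harmonised pair data.frame.
#' @return A list with `evaluable` (FALSE with fewer than 3 variants),
#'   `intercept`, `intercept_se`, `intercept_p`, `slope`, `slope_se`,
#'   `slope_p`.
#' @export
egger_intercept_test <- function(pairs) {
  if (nrow(pairs) < 3)
    return(list(evaluable = FALSE, intercept = NA_real_, intercept_se = NA_real_,
                intercept_p = NA_real_, slope = NA_real_, slope_se = NA_real_,
                slope_p = NA_real_))
  s <- sign(pairs$beta_exp)
  x <- pairs$beta_exp * s
  y <- pairs$beta_out * s
  w <- 1 / pairs$se_out^2
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  # rescale lm's SEs (which include the residual scale) to fixed-effect form
  co <- sm$coefficients
  se_fixed <- co[, "Std. Error"] / sm$sigma
  zi <- co["(Intercept)", "Estimate"] / se_fixed["(Intercept)"]
  zs <- co["x", "Estimate"] / se_fixed["x"]
  list(
    evaluable = TRUE,
    intercept = unname(co["(Intercept)", "Estimate"]),
    intercept_se = unname(se_fixed["(Intercept)"]),
    intercept_p = 2 * stats::pnorm(-abs(unname(zi))),
    slope = unname(co["x", "Estimate"]),
    slope_se = unname(se_fixed["x"]),
    slope_p = 2 * stats::pnorm(-abs(unname(zs)))
  )
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_j (theta_j - beta_ivw)^2 with w_j = 1/se_theta_j^2, df = n-1,
#' p from the upper chi-square tail.
#'
#' @param estimates Ratio-estimate data.frame.
#' @param beta_ivw The pooled IVW estimate the ratios are compared to.
#' @return A list with `evaluable`, `Q`, `df`, `p`.
#' @export
cochran_q <- function(estimates, beta_ivw) {
  if (nrow(estimates) < 2)
    return(list(evaluable = FALSE, Q = NA_real_, df = NA_real_, p = NA_real_))
  w <- 1 / estimates$se_theta^2
  Q <- sum(w * (estimates$theta - beta_ivw)^2)
  df <- nrow(estimates) - 1
  list(evaluable = TRUE, Q = Q, df = df,
       p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate q-values, q_(i) = min_{k >= i}
#' m p_(k) / k clipped at 1, returned in input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
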