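# Independent reference implementations used as oracles. These are kept
# deliberately naive (explicit loops, direct formulas) and separate from
# the package's code paths.

# greedy clumping re-implemented directly from the selection rule
oracle_clump <- function(assocs, ld, window_kb, r2_threshold, p_threshold) {
  remaining <- assocs[assocs$p < p_threshold, , drop = FALSE]
  remaining <- remaining[order(remaining$p, remaining$chr, remaining$pos), ,
                         drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept <- c(kept, idx$rsid)
    drop <- logical(nrow(remaining))
    drop[1] <- TRUE
    for (i in seq_len(nrow(remaining))[-1]) {
      same_chr <- remaining$chr[i] == idx$chr
      near <- abs(remaining$pos[i] - idx$pos) <= window_kb * 1000
      dependent <- if (is.null(ld)) TRUE else
        ld[idx$rsid, remaining$rsid[i]] >= r2_threshold
      if (same_chr && near && dependent) drop[i] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# weighted least squares (intercept + slope) by explicit normal equations,
# fixed-effect covariance (X'WX)^-1
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  XtWy <- t(X) %*% (w * y)
  coef <- solve(XtWX, XtWy)
  V <- solve(XtWX)
  list(intercept = coef[1], slope = coef[2],
       se_intercept = sqrt(V[1, 1]), se_slope = sqrt(V[2, 2]))
}

# BH step-up q-values computed literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(1, m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# OLS coefficient and SE via explicit normal equations
oracle_ols <- function(X, y) {
  XtX <- t(X) %*% X
  coef <- solve(XtX, t(X) %*% y)
  res <- y - X %*% coef
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  V <- sigma2 * solve(XtX)
  list(coef = as.vector(coef), se = unname(sqrt(diag(V))))
}

random_ratio_estimates <- function(n, theta_sd = 1, se_range = c(0.05, 0.5)) {
  data.frame(
    rsid = sprintf("rs%03d", seq_len(n)),
    theta = stats::rnorm(n, 0, theta_sd),
    se_theta = stats::runif(n, se_range[1], se_range[2]),
    stringsAsFactors = FALSE
  )
}

random_pairs <- function(n) {
  data.frame(
    rsid = sprintf("rs%03d", seq_len(n)),
    beta_exp = stats::runif(n, 0.02, 0.1) * sample(c(-1, 1), n, replace = TRUE),
    se_exp = stats::runif(n, 0.001, 0.01),
    n_exp = 5e5,
    beta_out = stats::rnorm(n, 0, 0.05),
    se_out = stats::runif(n, 0.005, 0.03),
    n_out = 2.5e5,
    stringsAsFactors = FALSE
  )
}

make_assoc <- function(rsid, chr = "1", pos = 1e6, ea = "A", oa = "G",
                       eaf = 0.3, beta = 0.05, se = 0.005, n = 5e5) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  data.frame(rsid = rsid, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, p = p, n = n, stringsAsFactors = FALSE)
}
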