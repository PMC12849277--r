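# Soft clustering of per-variant Wald ratios.
#
# Model: ratio estimate theta_j with known sampling SD sigma_j is assigned
# to one of
#   * K substantive clusters:  theta_j ~ Normal(mu_k, sigma_j^2)
#   * a null component:        theta_j ~ Normal(0,    sigma_j^2)
#   * a junk component:        theta_j ~ Uniform over a 3x-range interval
#                              around the observed ratios (heavy,
#                              location-free; absorbs outliers)
# with mixing proportions pi. Fitted by EM on the observed thetas; the
# per-variant variances are treated as known, so precision-weighted means
# are the M-step update for the mu_k.

pi_const <- base::pi

log_sum_exp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

junk_bounds <- function(theta) {
  r <- max(theta) - min(theta)
  if (r <= 0) {
    c(min(theta) - 0.5, max(theta) + 0.5)
  } else {
    c(min(theta) - r, max(theta) + r)
  }
}

# n x (K+2) matrix of log component densities (columns: clusters, null, junk)
component_log_density <- function(theta, sigma, means, junk, overdispersion = 1) {
  K <- length(means)
  s <- sigma * sqrt(overdispersion)
  dens <- matrix(NA_real_, length(theta), K + 2)
  for (k in seq_len(K))
    dens[, k] <- stats::dnorm(theta, means[k], s, log = TRUE)
  dens[, K + 1] <- stats::dnorm(theta, 0, s, log = TRUE)
  width <- junk[2] - junk[1]
  dens[, K + 2] <- ifelse(theta >= junk[1] & theta <= junk[2],
                          -log(width), -Inf)
  dens
}

#' Fit the ratio-estimate mixture model by EM for a fixed K
#'
#' Fits K substantive Normal clusters plus a zero-mean null component and
#' a uniform junk component to per-variant Wald ratios with known
#' standard errors. E-step computes per-variant responsibilities; M-step
#' updates each cluster mean as the responsibility- and precision-weighted
#' mean of the ratios and the mixing proportions as mean responsibilities.
#' Iterates until the log-likelihood improves by less than `tol`
#' (default 1e-8) or `max_iter` (default 5000) iterations; the
#' log-likelihood is non-decreasing across iterations (the EM guarantee),
#' and the fitted means are reported sorted ascending (canonical form,
#' removing label-switching ambiguity).
#'
#' @param estimates Ratio-estimate data.frame (columns theta, se_theta).
#' @param K Number of substantive clusters (>= 0).
#' @param seed Integer seed controlling the initial means when
#'   `init_means` is not given.
#' @param init_means Optional numeric vector of K starting means;
#'   defaults to an even grid over the observed ratio range.
#' @param overdispersion Variance inflation factor applied to every
#'   per-variant sigma (default 1, i.e. none).
#' @param tol,max_iter Convergence controls.
#' @return An object of class `mixture_model`: list with K, means, pi
#'   (named proportions over clusters, null, junk), log_likelihood, bic,
#'   trace (per-iteration log-likelihood), junk bounds, n, seed.
#' @export
fit_em <- function(estimates, K, seed = 1L, init_means = NULL,
                   overdispersion = 1, tol = 1e-8, max_iter = 5000L) {
  theta <- estimates$theta
  sigma <- estimates$se_theta
  n <- length(theta)
  if (K < 0) stop("K must be >= 0")
  if (n < K + 2) stop("need at least K + 2 estimates to fit K clusters")
  junk <- junk_bounds(theta)
  if (is.null(init_means)) {
    if (K > 0) {
      r <- range(theta)
      init_means <- r[1] + (seq_len(K) - 0.5) / K * (r[2] - r[1])
    } else {
      init_means <- numeric(0)
    }
  }
  if (length(init_means) != K) stop("init_means must have length K")
  fit <- em_fit_cpp(theta, sigma, sort(init_means), junk[1], junk[2],
                    overdispersion, tol, as.integer(max_iter))
  means <- fit$means
  pi <- fit$pi
  # canonical form: substantive means ascending
  if (K > 1) {
    ord <- order(means)
    means <- means[ord]
    pi <- c(pi[ord], pi[K + 1], pi[K + 2])
  }
  names(pi) <- c(if (K > 0) paste0("cluster_", seq_len(K)), "null", "junk")
  structure(list(
    K = K, means = means, pi = pi,
    log_likelihood = fit$log_likelihood,
    bic = -2 * fit$log_likelihood + (2 * K + 1) * log(n),
    trace = fit$trace, junk = junk, n = n, seed = seed,
    overdispersion = overdispersion, n_restarts = 1L
  ), class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat("Ratio-estimate mixture model\n")
  cat(sprintf("  K = %d substantive cluster(s), n = %d variants\n", x$K, x$n))
  if (x$K > 0)
    cat("  means:", paste(sprintf("%.4f", x$means), collapse = ", "), "\n")
  cat("  pi:", paste(sprintf("%s=%.3f", names(x$pi), x$pi), collapse = ", "), "\n")
  cat(sprintf("  logL = %.4f, BIC = %.4f\n", x$log_likelihood, x$bic))
  invisible(x)
}

#' Fit mixtures for K = 0..K_max and select by BIC
#'
#' For each K, runs `n_restarts` EM fits from seeded initial means spread
#' over the observed ratio range (an even grid, jittered per restart) and
#' keeps the best log-likelihood; the returned model is the K minimising
#' BIC = -2 logL + (2K + 1) log n (ties break toward smaller K). The
#' global `seed` fully determines the result, independent of input row
#' order.
#'
#' @param estimates Ratio-estimate data.frame.
#' @param K_max Largest number of substantive clusters to consider.
#' @param n_restarts Restarts per K (default 30).
#' @param seed Integer seed.
#' @return The selected `mixture_model`, with `bic_by_K` attached.
#' @export
select_model <- function(estimates, K_max, n_restarts = 30L, seed = 1L) {
  if (K_max < 0) stop("K_max must be >= 0")
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  set.seed(seed)
  r <- range(estimates$theta)
  span <- r[2] - r[1]
  best_by_K <- vector("list", K_max + 1)
  for (K in 0:K_max) {
    gw <- if (K > 0) span / K else 0
    best <- NULL
    for (rep in seq_len(if (K == 0) 1L else n_restarts)) {
      init <- if (K == 0) numeric(0) else {
        grid <- r[1] + (seq_len(K) - 0.5) / K * span
        if (rep == 1) grid else grid + stats::runif(K, -gw, gw)
      }
      fit <- fit_em(estimates, K, seed = seed, init_means = init)
      if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
    }
    best$n_restarts <- as.integer(if (K == 0) 1L else n_restarts)
    best_by_K[[K + 1]] <- best
  }
  bics <- vapply(best_by_K, `[[`, numeric(1), "bic")
  sel <- best_by_K[[which.min(bics)]]
  sel$seed <- seed
  attr(sel, "bic_by_K") <- stats::setNames(bics, paste0("K", 0:K_max))
  sel
}

#' Per-variant cluster assignment with small-cluster dissolution
#'
#' Computes the responsibility (inclusion probability) of every variant
#' for each mixture component, assigns a hard label by largest
#' responsibility, and flags a variant `confident` when that probability
#' reaches `prob_threshold`. Substantive clusters retaining fewer than
#' `min_cluster_size` confident members are dissolved: their members are
#' relabelled to their next-best surviving component (probability vectors
#' are left untouched, so they still sum to one). Dissolution repeats
#' until every surviving substantive cluster meets the size rule.
#'
#' @param model Fitted `mixture_model`.
#' @param estimates The ratio estimates the model was fitted on (or a
#'   compatible set), with columns rsid, theta, se_theta.
#' @param prob_threshold Confidence threshold on the assigned
#'   probability (default 0.8).
#' @param min_cluster_size Minimum confident members a substantive
#'   cluster must retain (default 4).
#' @return An object of class `cluster_assignment`: list with
#'   `assignments` (data.frame rsid, theta, se_theta, label, prob_label,
#'   confident), `responsibilities` (matrix), `counts` (confident members
#'   per surviving component) and `dissolved` (labels of dissolved
#'   clusters).
#' @export
assign_clusters <- function(model, estimates, prob_threshold = 0.8,
                            min_cluster_size = 4L) {
  comp_names <- names(model$pi)
  dens <- component_log_density(estimates$theta, estimates$se_theta,
                                model$means, model$junk, model$overdispersion)
  logw <- sweep(dens, 2, ifelse(model$pi > 0, log(model$pi), -Inf), `+`)
  resp <- exp(logw - log_sum_exp_rows(logw))
  colnames(resp) <- comp_names
  alive <- rep(TRUE, length(comp_names))
  names(alive) <- comp_names
  label_idx <- apply(resp, 1, which.max)
  dissolved <- character(0)
  repeat {
    prob_label <- resp[cbind(seq_len(nrow(resp)), label_idx)]
    confident <- prob_label >= prob_threshold
    subst <- which(alive & grepl("^cluster_", comp_names))
    sizes <- vapply(subst, function(k) sum(confident & label_idx == k), integer(1))
    small <- subst[sizes < min_cluster_size]
    if (length(small) == 0) break
    # dissolve the weakest cluster first
    victim <- small[which.min(sizes[match(small, subst)])]
    alive[victim] <- FALSE
    dissolved <- c(dissolved, comp_names[victim])
    moved <- which(label_idx == victim)
    for (j in moved) {
      cand <- which(alive)
      label_idx[j] <- cand[which.max(resp[j, cand])]
    }
  }
  prob_label <- resp[cbind(seq_len(nrow(resp)), label_idx)]
  confident <- prob_label >= prob_threshold
  assignments <- data.frame(
    rsid = estimates$rsid, theta = estimates$theta,
    se_theta = estimates$se_theta,
    label = comp_names[label_idx], prob_label = prob_label,
    confident = confident, stringsAsFactors = FALSE
  )
  counts <- table(factor(assignments$label[assignments$confident],
                         levels = comp_names[alive]))
  structure(list(
    assignments = assignments, responsibilities = resp,
    counts = counts, dissolved = dissolved,
    prob_threshold = prob_threshold, min_cluster_size = min_cluster_size
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment (confident members per component):\n")
  print(x$counts)
  if (length(x$dissolved) > 0)
    cat("  dissolved:", paste(x$dissolved, collapse = ", "), "\n")
  invisible(x)
}

#' Per-cluster IVW MR estimates
#'
#' For every surviving component except junk, pools the Wald ratios of its
#' confident members with fixed-effect IVW and reports the unweighted mean
#' of the member ratios alongside. Clusters with no confident members are
#' omitted (with a message).
#'
#' @param assignment A `cluster_assignment`.
#' @param pairs Harmonised pairs covering every confident variant.
#' @param second_order Passed to [wald_ratio()].
#' @return Data.frame with one row per reported cluster: cluster, n_snps,
#'   cluster_mean, beta, se, ci_lower, ci_upper, p, Q, Q_df, Q_p.
#' @export
cluster_ivw <- function(assignment, pairs, second_order = FALSE) {
  a <- assignment$assignments
  conf <- a[a$confident & a$label != "junk", , drop = FALSE]
  missing <- setdiff(conf$rsid, pairs$rsid)
  if (length(missing) > 0)
    stop("confident variants missing from pairs: ",
         paste(utils::head(missing, 5), collapse = ", "))
  comp <- names(assignment$counts)
  comp <- comp[comp != "junk"]
  rows <- list()
  for (cl in comp) {
    ids <- conf$rsid[conf$label == cl]
    if (length(ids) == 0) {
      message("cluster_ivw: no confident members in ", cl, "; omitted")
      next
    }
    pr <- pairs[match(ids, pairs$rsid), , drop = FALSE]
    ratios <- wald_ratio(pr, second_order = second_order)
    est <- ivw(ratios)
    rows[[cl]] <- data.frame(
      cluster = cl, n_snps = length(ids),
      cluster_mean = mean(ratios$theta),
      beta = est$beta, se = est$se,
      ci_lower = est$ci_lower, ci_upper = est$ci_upper, p = est$p,
      Q = est$Q, Q_df = est$Q_df, Q_p = est$Q_p,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
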