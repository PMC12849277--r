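# Reading, validating, harmonising and filtering GWAS summary statistics.
#
# The canonical tabular dialect used throughout the package is a data.frame
# with columns
#   rsid, chr, pos, ea, oa, eaf, beta, se, p, n
# where `ea` is the effect allele, `oa` the other allele, `beta`/`se` the
# per-allele association (trait SD units or log-OR) and `n` the effective
# sample size. `eaf` may be NA.

CANONICAL_COLS <- c("rsid", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")
MANDATORY_COLS <- c("rsid", "chr", "pos", "ea", "oa", "beta", "se", "p", "n")
VALID_ALLELES <- c("A", "C", "G", "T")

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

empty_exclusion_log <- function() {
  data.frame(rsid = character(), reason = character(), stringsAsFactors = FALSE)
}

add_exclusions <- function(log, rsid, reason) {
  if (length(rsid) == 0) return(log)
  rbind(log, data.frame(rsid = as.character(rsid), reason = reason,
                        stringsAsFactors = FALSE))
}

#' Read GWAS summary statistics into the canonical dialect
#'
#' Reads a delimited text file of per-variant summary associations, renames
#' columns to the canonical dialect via `column_map`, validates every row
#' against the variant-association invariants and drops (with logging) any
#' row that fails them.
#'
#' Validation enforces: single-nucleotide alleles in A/C/G/T with effect
#' allele distinct from the other allele (indels and multi-allelic records
#' are rejected), `se > 0`, `p` in (0, 1], `n > 0`, and `eaf` in (0, 1)
#' when present. All copies of a duplicated rsid are dropped. A reported
#' p-value more than two orders of magnitude away from the normal
#' approximation implied by beta/se triggers a warning but no exclusion.
#'
#' @param path Path to a tab- or whitespace-delimited text file with a
#'   header row.
#' @param column_map Optional named character vector mapping canonical
#'   names (`rsid`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`,
#'   `n`) to the column names used in the file, e.g.
#'   `c(rsid = "SNP", ea = "A1", ...)`. Canonical names absent from the
#'   map are looked up verbatim.
#' @return A list with `assoc`, a data.frame in the canonical dialect, and
#'   `exclusions`, a data.frame of (rsid, reason) for every dropped row.
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  cols <- stats::setNames(CANONICAL_COLS, CANONICAL_COLS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), CANONICAL_COLS)
    if (length(bad) > 0)
      stop("unknown canonical names in column_map: ", paste(bad, collapse = ", "))
    cols[names(column_map)] <- column_map
  }
  missing_mand <- MANDATORY_COLS[!cols[MANDATORY_COLS] %in% names(raw)]
  if (length(missing_mand) > 0)
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (mapped to '%s')", missing_mand, cols[missing_mand]),
               collapse = ", "))
  df <- data.frame(
    rsid = as.character(raw[[cols["rsid"]]]),
    chr  = as.character(raw[[cols["chr"]]]),
    pos  = as.numeric(raw[[cols["pos"]]]),
    ea   = toupper(as.character(raw[[cols["ea"]]])),
    oa   = toupper(as.character(raw[[cols["oa"]]])),
    eaf  = if (cols["eaf"] %in% names(raw)) as.numeric(raw[[cols["eaf"]]]) else NA_real_,
    beta = as.numeric(raw[[cols["beta"]]]),
    se   = as.numeric(raw[[cols["se"]]]),
    p    = as.numeric(raw[[cols["p"]]]),
    n    = as.numeric(raw[[cols["n"]]]),
    stringsAsFactors = FALSE
  )
  validate_associations(df)
}

#' Validate a canonical association table
#'
#' Applies the row-level invariants of [read_summary_stats()] to an
#' in-memory data.frame, returning retained rows and an exclusion log.
#'
#' @param df Data.frame in the canonical dialect.
#' @return A list with `assoc` and `exclusions` as in [read_summary_stats()].
#' @export
validate_associations <- function(df) {
  log <- empty_exclusion_log()
  bad_allele <- !(df$ea %in% VALID_ALLELES) | !(df$oa %in% VALID_ALLELES)
  log <- add_exclusions(log, df$rsid[bad_allele], "non-biallelic")
  same_allele <- !bad_allele & df$ea == df$oa
  log <- add_exclusions(log, df$rsid[same_allele], "allele-identical")
  bad_se <- !is.finite(df$se) | df$se <= 0
  log <- add_exclusions(log, df$rsid[bad_se & !bad_allele & !same_allele], "invalid-se")
  bad_p <- !is.finite(df$p) | df$p <= 0 | df$p > 1
  log <- add_exclusions(log, df$rsid[bad_p & !bad_se & !bad_allele & !same_allele], "invalid-p")
  bad_n <- !is.finite(df$n) | df$n <= 0
  log <- add_exclusions(log, df$rsid[bad_n & !bad_p & !bad_se & !bad_allele & !same_allele],
                        "invalid-n")
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  keep_so_far <- !(bad_allele | same_allele | bad_se | bad_p | bad_n)
  log <- add_exclusions(log, df$rsid[bad_eaf & keep_so_far], "invalid-eaf")
  keep <- keep_so_far & !bad_eaf
  df_ok <- df[keep, , drop = FALSE]
  # drop every copy of a duplicated rsid
  dup_ids <- unique(df_ok$rsid[duplicated(df_ok$rsid)])
  if (length(dup_ids) > 0) {
    is_dup <- df_ok$rsid %in% dup_ids
    log <- add_exclusions(log, df_ok$rsid[is_dup], "duplicate")
    df_ok <- df_ok[!is_dup, , drop = FALSE]
  }
  # p vs Z consistency: warn only
  z <- abs(df_ok$beta / df_ok$se)
  p_norm <- 2 * stats::pnorm(-z)
  with_p <- p_norm > 0 & df_ok$p > 0
  off <- with_p & abs(log10(df_ok$p) - log10(p_norm)) > 2
  if (any(off, na.rm = TRUE))
    warning(sum(off, na.rm = TRUE),
            " variant(s) report p-values inconsistent with beta/se by >2 orders of magnitude")
  rownames(df_ok) <- NULL
  list(assoc = df_ok, exclusions = log)
}

#' Write a canonical association table
#'
#' @param df Data.frame in the canonical dialect.
#' @param path Output path; a tab-delimited file with the canonical header
#'   is written.
#' @export
write_summary_stats <- function(df, path) {
  utils::write.table(df[, intersect(CANONICAL_COLS, names(df))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square LD matrix
#'
#' Reads a delimited square matrix of r-squared values with rsid labels as
#' both header row and first column; symmetry and a unit diagonal are
#' enforced.
#'
#' @param path Path to the delimited matrix.
#' @return A symmetric numeric matrix with rsid dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  validate_ld_matrix(m)
}

validate_ld_matrix <- function(m) {
  if (nrow(m) != ncol(m)) stop("LD matrix is not square")
  if (!isTRUE(all.equal(rownames(m), colnames(m))))
    stop("LD matrix row and column labels disagree")
  if (any(abs(m - t(m)) > 1e-8)) stop("LD matrix is not symmetric")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("LD matrix diagonal is not 1")
  if (any(m < -1e-8 | m > 1 + 1e-8)) stop("LD r-squared values outside [0,1]")
  m
}

#' Harmonise exposure and outcome associations to a shared effect allele
#'
#' For every rsid present in both tables, aligns the outcome association to
#' the exposure's effect/other allele pair: identical orientation is kept,
#' a swapped pair has its outcome beta sign-flipped (and eaf reflected),
#' and a complementary-strand pair is complemented first. Palindromic
#' variants (A/T or G/C), for which strand and swap are indistinguishable,
#' are resolved by allele frequency: the pair is kept only when both eafs
#' lie outside the ambiguity band `[maf_ambiguity_threshold, 1 -
#' maf_ambiguity_threshold]` and fall on the same side of 0.5 after
#' alignment; otherwise the variant is dropped as "palindromic-unresolved".
#' Irreconcilable allele pairs are dropped as "mismatch".
#'
#' @param exposure,outcome Canonical association data.frames.
#' @param maf_ambiguity_threshold Lower edge of the eaf ambiguity band
#'   (default 0.42, i.e. eaf in \[0.42, 0.58\] is unresolvable).
#' @return A list with `pairs`, a data.frame of harmonised pairs (columns
#'   rsid, chr, pos, ea, oa, eaf_exp, beta_exp, se_exp, n_exp, eaf_out,
#'   beta_out, se_out, n_out, palindromic, flipped), and `exclusions`.
#' @export
harmonise <- function(exposure, outcome, maf_ambiguity_threshold = 0.42) {
  thr <- maf_ambiguity_threshold
  shared <- intersect(exposure$rsid, outcome$rsid)
  if (length(shared) == 0) stop("no shared rsids between exposure and outcome")
  ei <- match(shared, exposure$rsid)
  oi <- match(shared, outcome$rsid)
  log <- empty_exclusion_log()
  rows <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    e <- exposure[ei[k], ]
    o <- outcome[oi[k], ]
    ea_o <- o$ea; oa_o <- o$oa; beta_o <- o$beta; eaf_o <- o$eaf
    pal <- is_palindromic_pair(e$ea, e$oa)
    flipped <- FALSE
    status <- "mismatch"
    if (!pal) {
      # strand complement first if the literal pair does not match
      if (!((ea_o == e$ea && oa_o == e$oa) || (ea_o == e$oa && oa_o == e$ea))) {
        ea_c <- unname(ALLELE_COMPLEMENT[ea_o])
        oa_c <- unname(ALLELE_COMPLEMENT[oa_o])
        if ((ea_c == e$ea && oa_c == e$oa) || (ea_c == e$oa && oa_c == e$ea)) {
          ea_o <- ea_c; oa_o <- oa_c
        }
      }
      if (ea_o == e$ea && oa_o == e$oa) {
        status <- "ok"
      } else if (ea_o == e$oa && oa_o == e$ea) {
        beta_o <- -beta_o
        if (!is.na(eaf_o)) eaf_o <- 1 - eaf_o
        flipped <- TRUE
        status <- "ok"
      }
    } else {
      # palindromic: same allele set required; swap alignment then eaf rule
      if (ea_o == e$ea && oa_o == e$oa) {
        status <- "check-eaf"
      } else if (ea_o == e$oa && oa_o == e$ea) {
        beta_o <- -beta_o
        if (!is.na(eaf_o)) eaf_o <- 1 - eaf_o
        flipped <- TRUE
        status <- "check-eaf"
      }
      if (status == "check-eaf") {
        resolvable <- !is.na(e$eaf) && !is.na(eaf_o) &&
          (e$eaf < thr || e$eaf > 1 - thr) &&
          (eaf_o < thr || eaf_o > 1 - thr) &&
          sign(e$eaf - 0.5) == sign(eaf_o - 0.5)
        status <- if (resolvable) "ok" else "palindromic-unresolved"
      }
    }
    if (status != "ok") {
      log <- add_exclusions(log, e$rsid, status)
      next
    }
    rows[[k]] <- data.frame(
      rsid = e$rsid, chr = e$chr, pos = e$pos, ea = e$ea, oa = e$oa,
      eaf_exp = e$eaf, beta_exp = e$beta, se_exp = e$se, n_exp = e$n,
      eaf_out = eaf_o, beta_out = beta_o, se_out = o$se, n_out = o$n,
      palindromic = pal, flipped = flipped, stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(rsid = character(), chr = character(), pos = numeric(),
                        ea = character(), oa = character(), eaf_exp = numeric(),
                        beta_exp = numeric(), se_exp = numeric(), n_exp = numeric(),
                        eaf_out = numeric(), beta_out = numeric(), se_out = numeric(),
                        n_out = numeric(), palindromic = logical(),
                        flipped = logical(), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, exclusions = log)
}

#' Greedy LD clumping
#'
#' Greedy index-variant selection: repeatedly retain the remaining variant
#' with the smallest p-value below `p_threshold` and remove all remaining
#' variants on the same chromosome within `window_kb` kilobases (closed
#' interval around the index position) whose r-squared with the index is at
#' least `r2_threshold`. Without an LD matrix the distance criterion alone
#' is applied (a message notes this). Ties in p-value break by (chr, pos)
#' ascending.
#'
#' @param assocs Canonical association data.frame.
#' @param ld Optional symmetric r-squared matrix with rsid dimnames
#'   covering the variants; `NULL` for distance-only clumping.
#' @param window_kb Window half-width in kb (default 500).
#' @param r2_threshold r-squared above which variants are dependent
#'   (default 0.001).
#' @param p_threshold Significance threshold for index variants (default
#'   5e-8).
#' @return Character vector of retained rsids in selection order.
#' @export
clump <- function(assocs, ld = NULL, window_kb = 500, r2_threshold = 0.001,
                  p_threshold = 5e-8) {
  if (is.null(ld)) {
    message("clump: no LD matrix supplied; using the distance criterion alone")
  }
  cand <- assocs[assocs$p < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  ord <- order(cand$p, cand$chr, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(cand))
  kept <- character(0)
  win <- window_kb * 1000
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    kept <- c(kept, cand$rsid[i])
    active[i] <- FALSE
    later <- which(active)
    if (length(later) == 0) break
    near <- cand$chr[later] == cand$chr[i] &
      abs(cand$pos[later] - cand$pos[i]) <= win
    if (!is.null(ld)) {
      r2 <- rep(NA_real_, length(later))
      have <- cand$rsid[i] %in% rownames(ld)
      if (have) {
        idx <- match(cand$rsid[later], rownames(ld))
        r2[!is.na(idx)] <- ld[cand$rsid[i], rownames(ld)[idx[!is.na(idx)]]]
      }
      # variants absent from the LD matrix are treated as uncorrelated
      near <- near & !is.na(r2) & r2 >= r2_threshold
    }
    active[later[near]] <- FALSE
  }
  kept
}

#' Steiger directionality filter
#'
#' Retains a harmonised pair only when its instrument explains
#' significantly more trait variance in the exposure than in the outcome.
#' Variance explained is the pseudo r-squared Z^2 / (Z^2 + n) with
#' Z = beta/se; the difference is tested one-sided via Fisher's
#' z-transform of r = sqrt(r-squared) with variance
#' 1/(n_exp - 3) + 1/(n_out - 3), under a normal approximation.
#'
#' @param pairs Harmonised pair data.frame from [harmonise()].
#' @param alpha One-sided significance level (default 0.05). `alpha = 1`
#'   reduces the filter to the pure direction condition.
#' @return A list with `pairs` (retained rows, plus columns r2_exp, r2_out
#'   and steiger_p) and `exclusions`.
#' @export
steiger_filter <- function(pairs, alpha = 0.05) {
  log <- empty_exclusion_log()
  if (nrow(pairs) == 0) return(list(pairs = pairs, exclusions = log))
  small_n <- !is.finite(pairs$n_exp) | !is.finite(pairs$n_out) |
    pairs$n_exp <= 3 | pairs$n_out <= 3
  log <- add_exclusions(log, pairs$rsid[small_n], "n-too-small")
  pr <- pairs[!small_n, , drop = FALSE]
  z_exp <- pr$beta_exp / pr$se_exp
  z_out <- pr$beta_out / pr$se_out
  r2_exp <- z_exp^2 / (z_exp^2 + pr$n_exp)
  r2_out <- z_out^2 / (z_out^2 + pr$n_out)
  fz <- function(r2) atanh(sqrt(r2))
  stat <- (fz(r2_exp) - fz(r2_out)) /
    sqrt(1 / (pr$n_exp - 3) + 1 / (pr$n_out - 3))
  p_one <- stats::pnorm(stat, lower.tail = FALSE)
  keep <- r2_exp > r2_out & p_one < alpha
  log <- add_exclusions(log, pr$rsid[!keep], "steiger-failed")
  out <- pr[keep, , drop = FALSE]
  out$r2_exp <- r2_exp[keep]
  out$r2_out <- r2_out[keep]
  out$steiger_p <- p_one[keep]
  rownames(out) <- NULL
  list(pairs = out, exclusions = log)
}
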