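# Instrument selection for molecular (protein) traits ahead of the
# mediator -> outcome MR step.

#' Select MR instruments for one molecular trait
#'
#' Keeps associations below `p_threshold`, clumps them to independence
#' with [clump()] (same window/r-squared defaults as the exposure
#' analysis), classifies each retained variant as cis when it lies on the
#' gene's chromosome within `cis_window_kb` of the gene interval, and
#' marks the trait eligible when at least `min_snps` independent
#' instruments remain of which at least `min_cis` are cis.
#'
#' @param assocs Canonical association data.frame for the trait.
#' @param locus List or one-row data.frame with chrom, start, end (gene
#'   coordinates); `NULL`/NA marks the locus unknown and the trait
#'   ineligible.
#' @param ld Optional LD matrix for clumping.
#' @param p_threshold Instrument significance threshold (default
#'   1.7e-11).
#' @param cis_window_kb Cis window around the gene interval in kb
#'   (default 1000, i.e. +/- 1 Mb).
#' @param window_kb,r2_threshold Clumping parameters (defaults 500 kb,
#'   0.001).
#' @param min_snps,min_cis Eligibility thresholds (defaults 3 and 1).
#' @return List of class `protein_instruments`: protein instruments
#'   data.frame (canonical columns plus `cis`), n_total, n_cis, eligible,
#'   and reason when ineligible.
#' @export
select_instruments <- function(assocs, locus, ld = NULL,
                               p_threshold = 1.7e-11, cis_window_kb = 1000,
                               window_kb = 500, r2_threshold = 0.001,
                               min_snps = 3L, min_cis = 1L) {
  unknown_locus <- is.null(locus) ||
    any(is.na(c(locus$chrom, locus$start, locus$end)))
  kept <- suppressMessages(
    clump(assocs, ld = ld, window_kb = window_kb,
          r2_threshold = r2_threshold, p_threshold = p_threshold)
  )
  inst <- assocs[match(kept, assocs$rsid), , drop = FALSE]
  if (unknown_locus) {
    inst$cis <- NA
    return(structure(list(instruments = inst, n_total = nrow(inst),
                          n_cis = NA_integer_, eligible = FALSE,
                          reason = "unknown-locus"),
                     class = "protein_instruments"))
  }
  win <- cis_window_kb * 1000
  inst$cis <- inst$chr == as.character(locus$chrom) &
    inst$pos >= locus$start - win & inst$pos <= locus$end + win
  n_total <- nrow(inst)
  n_cis <- sum(inst$cis)
  eligible <- n_total >= min_snps && n_cis >= min_cis
  reason <- if (eligible) NA_character_
    else if (n_total < min_snps) "too-few-instruments" else "no-cis-instrument"
  structure(list(instruments = inst, n_total = n_total, n_cis = n_cis,
                 eligible = eligible, reason = reason),
            class = "protein_instruments")
}

#' @export
print.protein_instruments <- function(x, ...) {
  cat(sprintf("Protein instrument set: %d instrument(s), %s cis, %s\n",
              x$n_total,
              ifelse(is.na(x$n_cis), "?", x$n_cis),
              if (x$eligible) "eligible" else paste0("ineligible (", x$reason, ")")))
  invisible(x)
}
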