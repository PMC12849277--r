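# Reading, harmonisation, clumping, Steiger filtering

write_stats_file <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("well-formed files round-trip with an empty exclusion log", {
  df <- do.call(rbind, lapply(1:5, function(i)
    make_assoc(sprintf("rs%d", i), pos = i * 1e6, beta = 0.01 * i)))
  res <- read_summary_stats(write_stats_file(df))
  expect_equal(nrow(res$assoc), 5)
  expect_equal(nrow(res$exclusions), 0)
  expect_equal(res$assoc$rsid, df$rsid)
  expect_equal(res$assoc$beta, df$beta)
})

test_that("duplicated rsids are dropped entirely and logged", {
  df <- rbind(make_assoc("rs1"), make_assoc("rs2", pos = 2e6),
              make_assoc("rs2", pos = 3e6), make_assoc("rs3", pos = 4e6),
              make_assoc("rs4", pos = 5e6))
  res <- read_summary_stats(write_stats_file(df))
  expect_equal(nrow(res$assoc), 3)
  expect_false("rs2" %in% res$assoc$rsid)
  expect_equal(sum(res$exclusions$reason == "duplicate"), 2)
})

test_that("non-biallelic and invalid rows are dropped with tagged reasons", {
  df <- rbind(make_assoc("rs1"), make_assoc("rs2", ea = "AT"),
              make_assoc("rs3", se = -1), make_assoc("rs4", ea = "G", oa = "G"))
  res <- read_summary_stats(write_stats_file(df))
  expect_equal(res$assoc$rsid, "rs1")
  log <- res$exclusions
  expect_equal(log$reason[log$rsid == "rs2"], "non-biallelic")
  expect_equal(log$reason[log$rsid == "rs3"], "invalid-se")
  expect_equal(log$reason[log$rsid == "rs4"], "allele-identical")
})

test_that("missing mandatory columns are a hard error naming the column", {
  df <- make_assoc("rs1")
  df$se <- NULL
  expect_error(read_summary_stats(write_stats_file(df)), "se")
})

test_that("column_map renames arbitrary headers to the canonical dialect", {
  df <- make_assoc("rs1")
  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ", "BETA", "SE", "P", "N")
  res <- read_summary_stats(write_stats_file(df),
                            column_map = c(rsid = "SNP", chr = "CHR",
                                           pos = "BP", ea = "A1", oa = "A2",
                                           eaf = "FRQ", beta = "BETA",
                                           se = "SE", p = "P", n = "N"))
  expect_equal(res$assoc$rsid, "rs1")
  expect_equal(res$assoc$beta, 0.05)
})

test_that("inconsistent reported p-values warn but are retained", {
  df <- make_assoc("rs1", beta = 0.05, se = 0.005)
  df$p <- 0.5  # Z = 10 implies p ~ 1.5e-23
  expect_warning(res <- validate_associations(df), "inconsistent")
  expect_equal(nrow(res$assoc), 1)
})

test_that("harmonise flips swapped alleles and reflects eaf", {
  exp <- make_assoc("rs1", ea = "A", oa = "G", beta = 0.1, eaf = 0.3)
  out <- make_assoc("rs1", ea = "G", oa = "A", beta = 0.05, eaf = 0.7)
  h <- harmonise(exp, out)
  expect_equal(nrow(h$pairs), 1)
  expect_equal(h$pairs$beta_out, -0.05)
  expect_equal(h$pairs$eaf_out, 0.3)
  expect_true(h$pairs$flipped)
  expect_false(h$pairs$palindromic)
})

test_that("complementary-strand records are aligned before orientation", {
  exp <- make_assoc("rs1", ea = "A", oa = "G", beta = 0.1)
  # T/C is the complement of A/G: same orientation once complemented
  out_same <- make_assoc("rs1", ea = "T", oa = "C", beta = 0.05)
  h <- harmonise(exp, out_same)
  expect_equal(h$pairs$beta_out, 0.05)
  expect_false(h$pairs$flipped)
  # C/T complements to G/A: swapped orientation
  out_swap <- make_assoc("rs1", ea = "C", oa = "T", beta = 0.05)
  h2 <- harmonise(exp, out_swap)
  expect_equal(h2$pairs$beta_out, -0.05)
  expect_true(h2$pairs$flipped)
})

test_that("palindromic pairs resolve only with concordant informative eafs", {
  exp <- make_assoc("rs1", ea = "A", oa = "T", eaf = 0.30)
  out <- make_assoc("rs1", ea = "A", oa = "T", eaf = 0.31)
  h <- harmonise(exp, out, maf_ambiguity_threshold = 0.42)
  expect_equal(nrow(h$pairs), 1)
  expect_true(h$pairs$palindromic)

  exp2 <- make_assoc("rs2", ea = "A", oa = "T", eaf = 0.49)
  out2 <- make_assoc("rs2", ea = "A", oa = "T", eaf = 0.30)
  h2 <- harmonise(exp2, out2)
  expect_equal(nrow(h2$pairs), 0)
  expect_equal(h2$exclusions$reason, "palindromic-unresolved")

  # discordant sides of 0.5 are ambiguous and dropped
  exp3 <- make_assoc("rs3", ea = "G", oa = "C", eaf = 0.2)
  out3 <- make_assoc("rs3", ea = "G", oa = "C", eaf = 0.8)
  h3 <- harmonise(exp3, out3)
  expect_equal(nrow(h3$pairs), 0)
})

test_that("irreconcilable allele pairs are dropped as mismatch", {
  exp <- make_assoc("rs1", ea = "A", oa = "G")
  out <- make_assoc("rs1", ea = "A", oa = "C")
  h <- harmonise(exp, out)
  expect_equal(nrow(h$pairs), 0)
  expect_equal(h$exclusions$reason, "mismatch")
})

test_that("harmonise is idempotent on its own output", {
  set.seed(11)
  cfg <- simulation_config(seed = 11,
                           clusters = data.frame(n_snps = 10, mean = 0.5),
                           n_null = 20)
  ss <- simulate_summary_stats(cfg)
  h1 <- harmonise(ss$exposure1, ss$outcome)
  expect_gt(nrow(h1$pairs), 0)
  exp2 <- data.frame(rsid = h1$pairs$rsid, chr = h1$pairs$chr,
                     pos = h1$pairs$pos, ea = h1$pairs$ea, oa = h1$pairs$oa,
                     eaf = h1$pairs$eaf_exp, beta = h1$pairs$beta_exp,
                     se = h1$pairs$se_exp, p = 1e-10, n = h1$pairs$n_exp,
                     stringsAsFactors = FALSE)
  out2 <- exp2
  out2$eaf <- h1$pairs$eaf_out
  out2$beta <- h1$pairs$beta_out
  out2$se <- h1$pairs$se_out
  out2$n <- h1$pairs$n_out
  h2 <- harmonise(exp2, out2)
  expect_equal(nrow(h2$pairs), nrow(h1$pairs))
  expect_false(any(h2$pairs$flipped))
  expect_equal(h2$pairs$beta_out, h1$pairs$beta_out)
})

test_that("clumping keeps distant index variants and drops dependent ones", {
  df <- rbind(
    make_assoc("SNP1", pos = 1e3, se = 0.0055),   # p ~ 1e-20
    make_assoc("SNP2", pos = 1e5, se = 0.0078),   # p ~ 1e-10
    make_assoc("SNP3", pos = 9e5, se = 0.0082))   # p ~ 1e-9
  ld <- matrix(0.5, 3, 3); diag(ld) <- 1
  dimnames(ld) <- list(df$rsid, df$rsid)
  kept <- suppressMessages(clump(df, ld = ld))
  expect_equal(kept, c("SNP1", "SNP3"))
})

test_that("clumping never crosses chromosomes and respects the p threshold", {
  df <- rbind(make_assoc("rs1", chr = "1", pos = 1e6),
              make_assoc("rs2", chr = "2", pos = 1e6))
  expect_setequal(suppressMessages(clump(df)), c("rs1", "rs2"))
  df_ns <- make_assoc("rs1", beta = 0.001, se = 0.005)  # p >> 5e-8
  expect_length(suppressMessages(clump(df_ns)), 0)
})

test_that("clumping matches the brute-force reference on random instances", {
  set.seed(91)
  for (rep in 1:25) {
    n <- sample(2:12, 1)
    df <- data.frame(
      rsid = sprintf("v%02d", seq_len(n)),
      chr = as.character(sample(1:3, n, replace = TRUE)),
      pos = sample(1e4:2e6, n),
      ea = "A", oa = "G", eaf = 0.3,
      beta = runif(n, 0.01, 0.1), se = runif(n, 0.002, 0.02),
      n = 5e5, stringsAsFactors = FALSE)
    df$p <- 2 * pnorm(-abs(df$beta / df$se))
    ld <- matrix(runif(n * n), n, n)
    ld <- (ld + t(ld)) / 2
    diag(ld) <- 1
    dimnames(ld) <- list(df$rsid, df$rsid)
    use_ld <- rep %% 2 == 0
    kept <- suppressMessages(
      clump(df, ld = if (use_ld) ld else NULL, window_kb = 300,
            r2_threshold = 0.4, p_threshold = 1e-4))
    ref <- oracle_clump(df, if (use_ld) ld else NULL, 300, 0.4, 1e-4)
    expect_equal(kept, ref)
    # retained set is independent: no pair violates the joint criterion
    if (length(kept) > 1) {
      sub <- df[match(kept, df$rsid), ]
      for (i in seq_along(kept)[-1]) for (j in seq_len(i - 1)) {
        violates <- sub$chr[i] == sub$chr[j] &&
          abs(sub$pos[i] - sub$pos[j]) <= 3e5 &&
          (!use_ld || ld[kept[i], kept[j]] >= 0.4)
        expect_false(violates)
      }
    }
  }
})

test_that("steiger filter retains instruments explaining more exposure variance", {
  # Z_exp = 10 on n = 500,000 vs Z_out = 0.5 on n = 240,000
  pr <- data.frame(rsid = "rs1", beta_exp = 0.1, se_exp = 0.01, n_exp = 5e5,
                   beta_out = 0.005, se_out = 0.01, n_out = 2.4e5)
  res <- steiger_filter(pr)
  # oracle: pseudo-r2 and Fisher z computed directly
  r2e <- 100 / (100 + 5e5); r2o <- 0.25 / (0.25 + 2.4e5)
  z <- (atanh(sqrt(r2e)) - atanh(sqrt(r2o))) / sqrt(1 / (5e5 - 3) + 1 / (2.4e5 - 3))
  expect_true(r2e > r2o && pnorm(z, lower.tail = FALSE) < 0.05)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$r2_exp, r2e)
  expect_equal(res$pairs$steiger_p, pnorm(z, lower.tail = FALSE))
})

test_that("steiger drops identical associations and reversed directions", {
  same <- data.frame(rsid = "rs1", beta_exp = 0.05, se_exp = 0.005, n_exp = 1e5,
                     beta_out = 0.05, se_out = 0.005, n_out = 1e5)
  expect_equal(nrow(steiger_filter(same)$pairs), 0)
  rev <- data.frame(rsid = "rs2", beta_exp = 0.01, se_exp = 0.005, n_exp = 1e5,
                    beta_out = 0.2, se_out = 0.005, n_out = 1e5)
  res <- steiger_filter(rev, alpha = 1)
  expect_equal(nrow(res$pairs), 0)
})

test_that("steiger with alpha 1 reduces to the direction condition", {
  set.seed(5)
  pr <- random_pairs(50)
  res <- steiger_filter(pr, alpha = 1)
  z_e <- (pr$beta_exp / pr$se_exp)^2
  z_o <- (pr$beta_out / pr$se_out)^2
  dir <- z_e / (z_e + pr$n_exp) > z_o / (z_o + pr$n_out)
  expect_setequal(res$pairs$rsid, pr$rsid[dir])
})

test_that("steiger tags variants with unusable sample sizes", {
  pr <- data.frame(rsid = "rs1", beta_exp = 0.1, se_exp = 0.01, n_exp = 2,
                   beta_out = 0.001, se_out = 0.01, n_out = 1e5)
  res <- steiger_filter(pr)
  expect_equal(res$exclusions$reason, "n-too-small")
})

test_that("LD matrices are validated for symmetry and unit diagonal", {
  m <- matrix(c(1, 0.2, 0.2, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  path <- tempfile()
  write.table(m, path, quote = FALSE)
  expect_equal(read_ld_matrix(path), m)
  bad <- m; bad[1, 2] <- 0.9
  expect_error(validate_ld_matrix(bad), "symmetric")
  bad2 <- m; diag(bad2) <- c(1, 0.5)
  expect_error(validate_ld_matrix(bad2), "diagonal")
})
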