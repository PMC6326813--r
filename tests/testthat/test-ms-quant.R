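mk_std <- function(id, peptides, intensities) {
  quant_table(id, "IAA", peptides, "primary", intensities)
}

test_that("response factors come from the mean of the two standards", {
  # identical intensities -> all factors 1
  f <- compute_norm_factors(mk_std("s1", c("A", "B"), c(5, 5)),
                            mk_std("s2", c("A", "B"), c(7, 7)),
                            reference = "A")
  expect_equal(f$factor, c(1, 1))
  # 2x ratio in both standards -> factor 2 (K- vs E-peptide scenario)
  f <- compute_norm_factors(mk_std("s1", c("E", "K"), c(100, 200)),
                            mk_std("s2", c("E", "K"), c(50, 100)),
                            reference = "E")
  expect_equal(f$factor[f$peptide == "K"], 2)
  expect_equal(f$factor[f$peptide == "E"], 1)
  # per-standard ratios 1.8 and 2.2 -> combined arithmetic mean 2.0
  f <- compute_norm_factors(mk_std("s1", c("E", "K"), c(100, 180)),
                            mk_std("s2", c("E", "K"), c(100, 220)),
                            reference = "E")
  expect_equal(f$factor[f$peptide == "K"], 2)
  # missing peptide or zero reference are errors
  expect_error(compute_norm_factors(mk_std("s1", "A", 1),
                                    mk_std("s2", c("A", "B"), c(1, 1)),
                                    reference = "A"),
               "missing from a standard")
  expect_error(compute_norm_factors(mk_std("s1", c("A", "B"), c(0, 1)),
                                    mk_std("s2", c("A", "B"), c(1, 1)),
                                    reference = "A"),
               "zero intensity|positive")
})

test_that("normalization divides by the factor and names missing peptides", {
  f <- compute_norm_factors(mk_std("s1", c("A", "B"), c(1, 2)),
                            mk_std("s2", c("A", "B"), c(1, 2)),
                            reference = "A")
  smp <- quant_table("r1", "IAA", c("A", "B"), "primary", c(1000, 1000))
  out <- normalize_quant(smp, f)
  expect_equal(out$intensity, c(1000, 500))
  expect_equal(out$raw_intensity, c(1000, 1000))
  expect_error(normalize_quant(
    quant_table("r1", "IAA", "ZZZ", "primary", 1), f), "ZZZ")
})

test_that("decoding fractions sum to 100, respect the threshold and scale invariance", {
  tab <- quant_table("r1", "IAC",
                     c("D_pep", "N_pep"), c("primary", "alternative"),
                     c(3, 1))
  res <- decoding_fractions(tab, "IAC")
  expect_equal(res$fractions$percent, c(75, 25))
  expect_equal(sum(res$fractions$percent), 100, tolerance = 1e-9)
  # sub-threshold alternative kept in the sum but flagged undetected
  tab <- quant_table("r1", "IAC", c("D_pep", "N_pep"),
                     c("primary", "alternative"), c(997, 3))
  res <- decoding_fractions(tab, "IAC")
  expect_equal(res$fractions$percent, c(99.7, 0.3))
  expect_false(res$fractions$detected[res$fractions$percent == 0.3])
  expect_true(res$fractions$detected[res$fractions$percent == 99.7])
  # single species -> 100%
  res <- decoding_fractions(quant_table("r1", "CUI", "L_pep", "primary",
                                        42), "CUI")
  expect_equal(res$fractions$percent, 100)
  # global rescaling leaves fractions unchanged
  tab2 <- tab
  tab2$intensity <- tab2$intensity * 1e3
  expect_equal(decoding_fractions(tab2, "IAC")$fractions$percent,
               res2 <- decoding_fractions(tab, "IAC")$fractions$percent)
  expect_error(decoding_fractions(
    quant_table("r1", "IAC", c("D_pep", "N_pep"),
                c("primary", "alternative"), c(0, 0)), "IAC"),
    "zero")
})

test_that("replicates are combined as mean of per-replicate fractions", {
  tab <- rbind(quant_table("r1", "IAC", c("D", "N"),
                           c("primary", "alternative"), c(80, 20)),
               quant_table("r2", "IAC", c("D", "N"),
                           c("primary", "alternative"), c(60, 40)))
  res <- decoding_fractions(validate_quant_table(tab), "IAC")
  expect_equal(res$fractions$percent, c(70, 30))
  expect_equal(res$n_replicates, 2L)
  # per-replicate fractions are 80/60 and 20/40: sd 10*sqrt(2), sem 10
  expect_equal(res$fractions$sem, rep(10, 2), tolerance = 1e-9)
})

test_that("truncation percentage uses truncated / (truncated + full-length)", {
  tab <- quant_table("r1", "III", c("full", "trunc"),
                     c("primary", "truncated"), c(64, 36))
  expect_equal(as.numeric(truncation_percent(tab, "III")), 36)
  tab0 <- quant_table("r1", "AAI", c("full", "trunc"),
                      c("primary", "truncated"), c(100, 0))
  expect_equal(as.numeric(truncation_percent(tab0, "AAI")), 0)
  # at/below the 0.4% detection threshold -> reported 0
  tab_lo <- quant_table("r1", "AIC", c("full", "trunc"),
                        c("primary", "truncated"), c(99.7, 0.3))
  expect_equal(as.numeric(truncation_percent(tab_lo, "AIC")), 0)
  expect_error(truncation_percent(
    quant_table("r1", "III", c("full", "trunc"),
                c("primary", "truncated"), c(0, 0)), "III"),
    "zero denominator")
})

test_that("read-through percentage behaves at 0, 50 and paper-band values", {
  tab <- quant_table("r1", "UAI", c("rt", "term"),
                     c("readthrough", "terminated"), c(1.5, 98.5))
  expect_equal(as.numeric(readthrough_percent(tab, "UAI")), 1.5)
  tab <- quant_table("r1", "UIA", c("rt", "term"),
                     c("readthrough", "terminated"), c(0, 100))
  expect_equal(as.numeric(readthrough_percent(tab, "UIA")), 0)
  tab <- quant_table("r1", "UAI", c("rt", "term"),
                     c("readthrough", "terminated"), c(5, 5))
  expect_equal(as.numeric(readthrough_percent(tab, "UAI")), 50)
})

test_that("truncation grouping reproduces the measured-table summaries", {
  tb <- load_truncation_table()
  expect_equal(nrow(tb), 31L)
  expect_equal(sum(tb$truncation_percent > 0), 28L)
  g <- group_truncation(tb, by = "inosine_count")
  expect_equal(g$n, c(21, 9, 1))
  expect_equal(g$mean_truncation, c(5.24, 28.44, 36))
  p <- group_truncation(tb, by = "single_inosine_position")
  expect_equal(p$n, c(9, 8, 4))
  expect_equal(p$mean_truncation, c(3, 3.5, 13.75))
  # degenerate groupings
  one <- data.frame(codon = "IAC", truncation_percent = 12)
  expect_equal(suppressWarnings(
    group_truncation(one, by = "inosine_count"))$mean_truncation, 12)
  zero <- data.frame(codon = c("IAC", "AIC"),
                     truncation_percent = c(0, 0))
  expect_equal(group_truncation(zero,
                                by = "inosine_count")$mean_truncation, 0)
})

test_that("quant tables are validated", {
  expect_error(quant_table("r1", "IAC", c("A", "A"), "primary", c(1, 2)),
               "one row per")
  expect_error(quant_table("r1", "IAC", "A", "primary", -1),
               "non-negative")
})
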