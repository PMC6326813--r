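flat_track <- function(L = 2000, value = 4) rep(value, L)

test_that("editing rate is g/(a+g) with undefined zero-depth sites", {
  expect_equal(editing_rate(80, 20), 0.2)
  expect_equal(editing_rate(100, 0), 0)
  expect_equal(editing_rate(0, 50), 1)
  expect_true(is.na(editing_rate(0, 0)))
  expect_equal(editing_rate(c(80, 0), c(20, 50)), c(0.2, 1))
})

test_that("neighbor filtering excludes transcripts with clustered sites", {
  s <- data.frame(transcript_id = c("t1", "t1", "t2", "t2", "t3"),
                  position = c(100, 104, 100, 106, 500))
  out <- filter_neighbor_sites(s, radius = 5)
  expect_false("t1" %in% out$transcript_id)   # distance 4 <= 5
  expect_true(all(c("t2", "t3") %in% out$transcript_id))  # 6 > 5; single
  expect_equal(sum(out$transcript_id == "t2"), 2L)
})

test_that("CDS selection takes the longest, ties broken by transcript id", {
  cand <- data.frame(transcript_id = c("b", "a"),
                     cds_start = c(0, 0), cds_end = c(300, 900))
  expect_equal(select_cds(cand)$transcript_id, "a")
  tie <- data.frame(transcript_id = c("b", "a"),
                    cds_start = c(0, 0), cds_end = c(600, 600))
  expect_equal(select_cds(tie)$transcript_id, "a")
  one <- data.frame(transcript_id = "x", cds_start = 10, cds_end = 70)
  expect_equal(select_cds(one)$transcript_id, "x")
})

test_that("codon position is 1 + (pos - cds_start) mod 3", {
  expect_equal(codon_position(10, 10), 1L)
  expect_equal(codon_position(14, 10), 2L)
  expect_equal(codon_position(18, 10), 3L)
  expect_true(is.na(codon_position(5, 10)))
  expect_true(is.na(codon_position(200, 10, 100)))
})

test_that("window normalization divides by the window total and masks edges", {
  pr <- metagene_params(norm_window = 500, display_window = 125)
  tr <- flat_track(2000, 3)
  v <- normalize_site_window(tr, 1000, pr)
  expect_length(v, 251L)
  expect_equal(unname(v["0"]), 1 / 1001)
  expect_equal(unname(v["-125"]), 1 / 1001)
  # scale invariance
  expect_equal(normalize_site_window(tr * 7, 1000, pr), v)
  # site 100 nt from the 5' end: positions < -100 masked, not zero
  v2 <- normalize_site_window(tr, 100, pr)
  expect_true(all(is.na(v2[as.integer(names(v2)) < -100])))
  expect_false(anyNA(v2[as.integer(names(v2)) >= -100]))
  # zero window total -> dropped
  expect_null(normalize_site_window(rep(0, 2000), 1000, pr))
})

test_that("weighted metagene honors editing-rate weights", {
  pr <- metagene_params(norm_window = 100, display_window = 20)
  tracks <- list(t1 = flat_track(1000, 2), t2 = flat_track(1000, 2))
  tracks$t2[481:521] <- 0          # distinctive profile for t2
  tracks$t2[300] <- 50             # keep window total positive
  sites <- data.frame(transcript_id = c("t1", "t2"),
                      position = c(500, 500),
                      editing_rate = c(1, 0))
  m <- metagene(tracks, sites, pr)
  only_t1 <- metagene(tracks, sites[1, ], pr)
  expect_equal(m$value, only_t1$value)  # rate-0 site is a no-op
  # identical profiles: metagene equals the profile for any weights
  sites2 <- data.frame(transcript_id = c("t1", "t1"),
                       position = c(500, 500),
                       editing_rate = c(0.9, 0.1))
  m2 <- metagene(list(t1 = flat_track(1000, 2)), sites2, pr)
  expect_true(all(abs(m2$value - 1 / 201) < 1e-12))
})

test_that("metagene is invariant under coverage rescaling and site order", {
  set.seed(31)
  sim <- sim_ribo_dataset(n_transcripts = 30, transcript_length = 1500,
                          mean_coverage = 5, dip = 0.5,
                          editing_rates = c(2, 2), prop_edited = 1,
                          cds_margin = 100, seed = 31)
  sites <- annotate_sites(sim$sites, sim$cds)
  pr <- metagene_params(norm_window = 300, display_window = 100)
  m1 <- metagene(sim$tracks, sites, pr)
  scaled <- lapply(sim$tracks, function(x) x * 13)
  m2 <- metagene(scaled, sites, pr)
  expect_equal(m1$value, m2$value, tolerance = 1e-12)
  perm <- sites[sample(nrow(sites)), , drop = FALSE]
  m3 <- metagene(sim$tracks, perm, pr)
  expect_equal(m1$value, m3$value, tolerance = 1e-12)
})

test_that("site annotation computes rate, status, codon position and depth guard", {
  sites <- data.frame(transcript_id = c("t1", "t1", "t2"),
                      position = c(12, 40, 5),
                      a_count = c(80, 100, 3),
                      g_count = c(20, 0, 2))
  cds <- data.frame(transcript_id = c("t1", "t2"),
                    cds_start = c(10, 0), cds_end = c(100, 50))
  expect_message(out <- annotate_sites(sites, cds,
                                       metagene_params(min_reads = 10)),
                 "dropped")
  expect_equal(nrow(out), 2L)
  expect_equal(out$status, c("edited", "unedited"))
  expect_equal(out$codon_position, c(3L, 1L))
})

test_that("position-split analysis returns one profile per codon position", {
  sim <- sim_ribo_dataset(n_transcripts = 45, transcript_length = 1200,
                          mean_coverage = 8, dip = 0.5,
                          editing_rates = 1, prop_edited = 1,
                          cds_margin = 60, seed = 13)
  sites <- annotate_sites(sim$sites, sim$cds)
  pr <- metagene_params(norm_window = 400, display_window = 50)
  ps <- position_split_metagene(sim$tracks, sites, pr)
  expect_setequal(names(ps), c("pos1", "pos2", "pos3"))
  # all sites at one position: other groups empty with warning,
  # remaining group equals the plain metagene
  s1 <- sites[sites$codon_position == 1L, , drop = FALSE]
  # both empty groups (positions 2 and 3) warn
  expect_warning(expect_warning(
    ps1 <- position_split_metagene(sim$tracks, s1, pr), "omitted"),
    "omitted")
  expect_equal(names(ps1), "pos1")
  expect_equal(ps1$pos1$value, metagene(sim$tracks, s1, pr)$value)
})
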