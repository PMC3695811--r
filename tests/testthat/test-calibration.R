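test_that("build_truth_set matches on position and alleles within the target", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 1000))
  calls <- data.table(chrom = "chr1", pos = c(100L, 200L, 2000L),
                      ref = "A", alt = "G",
                      genotype = c("het", "het", "hom"), qual = c(50, 20, 50),
                      depth = 10L)
  panel <- data.table(chrom = "chr1", pos = c(100L, 200L, 2000L),
                      ref = "A", alt = c("G", "T", "G"))
  truth <- build_truth_set(calls, panel, target)
  # pos 100 matches; pos 200 has mismatched alleles; pos 2000 is off target
  expect_equal(truth$pos, 100L)
  expect_equal(attr(truth, "n_allele_mismatch"), 1L)
  # symmetric quality filter
  truth_q <- build_truth_set(calls, panel, target, qual_filter = 30)
  expect_equal(truth_q$pos, 100L)
  expect_equal(build_truth_set(calls[qual >= 60], panel, target)$pos, integer(0))
})

test_that("truth-set size equals the brute-force triple intersection on random data", {
  set.seed(33)
  target <- merge_intervals(genomic_intervals("chr1", c(0, 500), c(300, 900)))
  acgt <- c("A", "C", "G", "T")
  rnd_sites <- function(n) {
    ref <- sample(acgt, n, TRUE)
    data.table(chrom = "chr1", pos = sample.int(1000L, n) - 1L, ref = ref,
               alt = vapply(ref, function(r) sample(setdiff(acgt, r), 1L), ""))
  }
  calls <- unique(rnd_sites(200L), by = c("chrom", "pos"))
  calls[, `:=`(genotype = sample(c("het", "hom"), .N, TRUE), qual = 60, depth = 9L)]
  panel <- unique(rnd_sites(200L), by = c("chrom", "pos"))
  truth <- build_truth_set(calls, panel, target)
  # oracle: plain loops over the three conditions
  n_expect <- 0L
  for (i in seq_len(nrow(calls))) {
    in_target <- any(calls$pos[i] >= target$intervals$start &
                       calls$pos[i] < target$intervals$end)
    hit <- panel[pos == calls$pos[i] & ref == calls$ref[i] & alt == calls$alt[i]]
    if (in_target && nrow(hit) == 1L) n_expect <- n_expect + 1L
  }
  expect_equal(nrow(truth), n_expect)
})

test_that("classification assigns the partial-true-positive taxonomy and FN depth", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 100))
  truth <- data.table(chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A",
                      alt = "G", genotype = c("het", "hom", "het"))
  ds_calls <- data.table(chrom = "chr1", pos = c(10L, 20L), ref = "A",
                         alt = "G", genotype = c("hom", "het"), qual = 40,
                         depth = 5L)
  depth <- structure(list(target = target, depth = rep(4L, 100L)),
                     class = "depth_profile")
  cls <- classify_downsampled(truth, ds_calls, depth, p = 0.3)
  expect_equal(cls$outcome, c("PTP_het_called_hom", "PTP_hom_called_het", "FN"))
  expect_equal(cls$depth_at_site, c(4L, 4L, 4L))
  expect_equal(unique(cls$downsample_p), 0.3)

  # truth site outside the profile target is a contract violation
  bad_truth <- rbind(truth, data.table(chrom = "chr1", pos = 500L, ref = "A",
                                       alt = "G", genotype = "het"))
  expect_error(classify_downsampled(bad_truth, ds_calls, depth, p = 0.3),
               class = "senscall_contract_error")
})

test_that("a 20-site fixture reproduces its hand-computed confusion table", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 2000))
  # 20 truth sites: 12 het, 8 hom
  truth <- data.table(chrom = "chr1", pos = seq(0L, 1900L, by = 100L),
                      ref = "A", alt = "C",
                      genotype = rep(c("het", "hom"), c(12L, 8L)))
  # calls: het sites 1-6 correct, 7-8 miscalled hom, 9-12 missing;
  #        hom sites 13-17 correct, 18 miscalled het, 19-20 missing
  ds_calls <- data.table(
    chrom = "chr1",
    pos = truth$pos[c(1:8, 13:18)], ref = "A", alt = "C",
    genotype = c(rep("het", 6L), rep("hom", 2L), rep("hom", 5L), "het"),
    qual = 50, depth = 7L)
  prof <- structure(list(target = target, depth = rep(6L, 2000L)),
                    class = "depth_profile")
  cls <- classify_downsampled(truth, ds_calls, prof, p = 0.5, replicate_id = 1L)
  expect_equal(nrow(cls), 20L)  # partition: one outcome per truth record
  tab <- table(cls$true_genotype, cls$outcome)
  expect_equal(unname(tab["het", "TP"]), 6L)
  expect_equal(unname(tab["het", "PTP_het_called_hom"]), 2L)
  expect_equal(unname(tab["het", "FN"]), 4L)
  expect_equal(unname(tab["hom", "TP"]), 5L)
  expect_equal(unname(tab["hom", "PTP_hom_called_het"]), 1L)
  expect_equal(unname(tab["hom", "FN"]), 2L)
})

test_that("sensitivity_curve applies TP/(TP+PTP+FN) in both binning modes", {
  cls <- data.table(chrom = "chr1", pos = 1:3, true_genotype = "het",
                    outcome = c("TP", "PTP_het_called_hom", "FN"),
                    depth_at_site = c(3L, 3L, 5L), downsample_p = 0.5,
                    replicate_id = 1L)
  cum <- sensitivity_curve(cls, "het", "cumulative_le_d", max_depth = 10L)
  expect_equal(cum[depth == 3, sensitivity], 1 / 2)
  expect_equal(cum[depth == 5, sensitivity], 1 / 3)
  expect_true(is.na(cum[depth == 2, sensitivity]))  # empty denominator
  ex <- sensitivity_curve(cls, "het", "exact_d", max_depth = 10L)
  expect_equal(ex[depth == 3, sensitivity], 1 / 2)
  expect_equal(ex[depth == 5, sensitivity], 0)
  expect_true(is.na(ex[depth == 4, sensitivity]))

  all_tp <- copy(cls)[, outcome := "TP"]
  cur <- sensitivity_curve(all_tp, "het", "exact_d", max_depth = 10L)
  expect_true(all(cur[!is.na(sensitivity), sensitivity] == 1))

  # depths above max_depth clamp into the top row
  deep <- copy(cls)[, depth_at_site := c(3L, 150L, 120L)]
  cur <- sensitivity_curve(deep, "het", "exact_d", max_depth = 100L)
  expect_equal(cur[depth == 100, n_ptp + n_fn], 2L)
})

test_that("classification partitions pooled over random worlds sum to truth size", {
  ex <- sim_world(seed = 55L, n_targets = 10L, mean_depth = 20,
                  het_site_rate = 0.01, hom_site_rate = 0.01)
  cal <- run_calibration(ex$reads, ex$truth[, .(chrom, pos, ref, alt)],
                         ex$target, ex$reference,
                         probabilities = c(0.2, 0.5, 0.8), seed = 55L)
  per_p <- cal$classifications[, .N, by = downsample_p]
  expect_true(all(per_p$N == nrow(cal$truth)))
  # curve counts conserve the classification totals
  for (g in c("het", "hom")) {
    cur <- cal$curves[genotype == g]
    expect_equal(sum(cur$n_tp + cur$n_ptp + cur$n_fn),
                 nrow(cal$classifications[true_genotype == g]))
  }
  # cumulative mode: denominator non-decreasing, sensitivity within [0, 1]
  cum <- cal$curves_cumulative[genotype == "het"]
  expect_true(!is.unsorted(cum$n_tp + cum$n_ptp + cum$n_fn))
  s <- cum$sensitivity[!is.na(cum$sensitivity)]
  expect_true(all(s >= 0 & s <= 1))
})

test_that("binomial_expectation enumerates the idealized caller", {
  # one read cannot yield a confident het at the default threshold
  expect_equal(binomial_expectation(1, "het", q = 30), 0)
  expect_equal(binomial_expectation(0, "het"), 0)
  # threshold 0 with near-perfect reads: only k = 1 of 2 gives het -> 0.5
  lax <- caller_params(call_threshold = 0)
  expect_equal(binomial_expectation(2, "het", lax, q = 90), 0.5)
  # hom, d = 3, defaults: enumeration vs Monte-Carlo through the decision rule
  e_hom <- binomial_expectation(3, "hom", q = 30)
  e_het <- binomial_expectation(10, "het", q = 30)
  set.seed(99)
  k <- rbinom(1e5, 10, 0.5)
  mc <- mean(vapply(k, function(kk)
    senscall:::decide_genotype(10 - kk, kk, 30)$genotype == "het", TRUE))
  expect_lt(abs(mc - e_het), 3 * sqrt(e_het * (1 - e_het) / 1e5))
  expect_equal(e_hom, 1)  # three q30 alt reads clear Q30 deterministically
})

test_that("genotype_concordance compares shared sites by class of set A", {
  calls <- data.table(chrom = "chr1", pos = 1:10, ref = "A", alt = "G",
                      genotype = "het", qual = 50, depth = 10L)
  expect_equal(genotype_concordance(calls, calls)$het, 1)
  flipped <- copy(calls)[1, genotype := "hom"]
  r <- genotype_concordance(calls, flipped)
  expect_equal(r$het, 0.9)
  expect_true(is.na(r$hom))  # A has no homs: undefined, flagged

  set.seed(77)
  n <- 4000L
  acgt <- c("A", "C", "G", "T")
  ref <- sample(acgt, n, TRUE)
  a <- data.table(chrom = "chr1", pos = seq_len(n), ref = ref,
                  alt = vapply(ref, function(r) sample(setdiff(acgt, r), 1L), ""),
                  genotype = sample(c("het", "hom"), n, TRUE), qual = 50,
                  depth = 10L)
  rate <- 0.05
  b <- copy(a)
  flip <- runif(n) < rate
  b[flip, genotype := ifelse(genotype == "het", "hom", "het")]
  r <- genotype_concordance(a, b)
  for (g in c("het", "hom")) {
    ng <- r[[paste0("n_", g)]]
    expect_lt(abs(r[[g]] - (1 - rate)), 3 * sqrt(rate * (1 - rate) / ng))
  }
})

test_that("run_calibration validates the probability grid", {
  ex <- sim_world(seed = 2L, n_targets = 3L, mean_depth = 5)
  panel <- ex$truth[, .(chrom, pos, ref, alt)]
  expect_error(run_calibration(ex$reads, panel, ex$target, ex$reference,
                               probabilities = c(0.5, 0.5)),
               class = "senscall_input_error")
  expect_error(run_calibration(ex$reads, panel, ex$target, ex$reference,
                               probabilities = c(0.9, 0.1)),
               class = "senscall_input_error")
  expect_error(run_calibration(ex$reads, panel, ex$target, ex$reference,
                               probabilities = c(0, 0.5)),
               class = "senscall_input_error")
})
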