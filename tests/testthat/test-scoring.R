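random_table <- function(seed = 1L, max_depth = 50L) {
  set.seed(seed)
  rbind(data.table(depth = 0:max_depth, genotype = "het",
                   n_tp = NA_integer_, n_ptp = NA_integer_, n_fn = NA_integer_,
                   sensitivity = c(0, sort(runif(max_depth)))),
        data.table(depth = 0:max_depth, genotype = "hom",
                   n_tp = NA_integer_, n_ptp = NA_integer_, n_fn = NA_integer_,
                   sensitivity = c(0, sort(runif(max_depth)))))
}

random_profile <- function(target, seed = 2L, max_depth = 60L) {
  set.seed(seed)
  structure(list(target = target,
                 depth = sample(0:max_depth, target_width(target), TRUE)),
            class = "depth_profile")
}

test_that("per_base_sensitivity maps depth through the table with clamping", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 200))
  tab <- random_table(max_depth = 50L)
  prof <- structure(list(target = target, depth = rep(0L, 200L)),
                    class = "depth_profile")
  track <- per_base_sensitivity(prof, tab)
  expect_true(all(track$het == 0) && all(track$hom == 0))

  prof$depth <- rep(7L, 200L)
  track <- per_base_sensitivity(prof, tab)
  expect_true(all(track$het == tab[genotype == "het" & depth == 7, sensitivity]))

  # random profile equals the brute-force per-position lookup, with depths
  # above the table maximum clamped to the top row
  prof <- random_profile(target, max_depth = 60L)
  track <- per_base_sensitivity(prof, tab)
  het_tab <- tab[genotype == "het"]
  brute <- vapply(prof$depth, function(d)
    het_tab[depth == min(d, 50L), sensitivity], numeric(1))
  expect_equal(track$het, brute)

  # undefined row at an occurring depth errors with the missing depths
  holey <- tab[!(genotype == "het" & depth == 7)]
  prof$depth <- rep(7L, 200L)
  expect_error(per_base_sensitivity(prof, holey), "7",
               class = "senscall_input_error")
})

test_that("region aggregation conserves the length-weighted mean", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 1000))
  tab <- random_table(seed = 5L)
  prof <- random_profile(target, seed = 6L)
  track <- per_base_sensitivity(prof, tab)

  # random partition of the target into contiguous regions
  set.seed(7)
  cuts <- sort(sample(1:999, 12L))
  bounds <- c(0L, cuts, 1000L)
  regions <- genomic_intervals("chr1", head(bounds, -1L), tail(bounds, -1L),
                               label = sprintf("r%02d", seq_len(13L)))
  rep <- aggregate_regions(track, regions)
  expect_equal(sum(rep$het_mean * rep$length) / sum(rep$length),
               mean(track$het), tolerance = 1e-12)
  expect_equal(sum(rep$hom_mean * rep$length) / sum(rep$length),
               mean(track$hom), tolerance = 1e-12)

  # two equal-length regions with means 0.8 and 1.0 -> whole mean 0.9
  t2 <- merge_intervals(genomic_intervals("chr1", 0, 10))
  tab2 <- rbind(data.table(depth = 0:2, genotype = "het", n_tp = NA_integer_,
                           n_ptp = NA_integer_, n_fn = NA_integer_,
                           sensitivity = c(0, 0.8, 1.0)),
                data.table(depth = 0:2, genotype = "hom", n_tp = NA_integer_,
                           n_ptp = NA_integer_, n_fn = NA_integer_,
                           sensitivity = c(0, 0.9, 1.0)))
  p2 <- structure(list(target = t2, depth = rep(c(1L, 2L), each = 5L)),
                  class = "depth_profile")
  tr2 <- per_base_sensitivity(p2, tab2)
  r2 <- aggregate_regions(tr2, genomic_intervals("chr1", c(0, 5), c(5, 10)))
  expect_equal(r2$het_mean, c(0.8, 1.0))
  expect_equal(mean(tr2$het), 0.9)

  # single-base region: mean = min; off-target region flagged undefined
  r1 <- aggregate_regions(tr2, genomic_intervals("chr1", c(3, 500), c(4, 600)))
  expect_equal(r1$het_mean[1], r1$het_min[1])
  expect_true(is.na(r1$het_mean[2]) && r1$length[2] == 0L)
})

test_that("total_sensitivity is the mean of the per-base track", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 500))
  tab <- random_table(seed = 9L)
  prof <- random_profile(target, seed = 10L)
  tot <- total_sensitivity(prof, tab)
  track <- per_base_sensitivity(prof, tab)
  expect_equal(unname(tot["het"]), mean(track$het))
  expect_equal(unname(tot["hom"]), mean(track$hom))

  # half at sensitivity 1, half at 0 -> 0.5
  tab01 <- rbind(data.table(depth = 0:1, genotype = "het", n_tp = NA_integer_,
                            n_ptp = NA_integer_, n_fn = NA_integer_,
                            sensitivity = c(0, 1)),
                 data.table(depth = 0:1, genotype = "hom", n_tp = NA_integer_,
                            n_ptp = NA_integer_, n_fn = NA_integer_,
                            sensitivity = c(0, 1)))
  prof$depth <- rep(c(0L, 1L), length.out = 500L)
  expect_equal(unname(total_sensitivity(prof, tab01)["het"]), 0.5)
})

test_that("required_mean_depth interpolates isotonic crossings and flags unattained levels", {
  r <- required_mean_depth(c(10, 20), c(0.8, 0.9), levels = 0.85)
  expect_equal(r$depth, 15)
  r <- required_mean_depth(c(10, 20), c(0.8, 0.9), levels = c(0.8, 0.95))
  expect_equal(r$depth[1], 10)
  expect_false(r$attained[2])
  expect_true(is.na(r$depth[2]))
  expect_error(required_mean_depth(10, 0.8), class = "senscall_input_error")

  # noisy monotone series: estimates bracket the true crossing, monotone in level
  set.seed(12)
  x <- seq(1, 60, by = 1)
  y_true <- 1 - exp(-x / 10)
  y <- pmin(pmax(y_true + rnorm(length(x), 0, 0.004), 0), 1)
  r <- required_mean_depth(x, y, levels = c(0.8, 0.9, 0.95))
  true_cross <- vapply(c(0.8, 0.9, 0.95), function(l) -10 * log(1 - l), 1)
  expect_true(all(abs(r$depth - true_cross) <= 2))
  expect_true(!is.unsorted(r$depth))
})

test_that("tile classification implements the well-covered / difficult / easy rules", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 300))
  tiles <- tile_targets(target, 100L)
  # tile 1: 95 bases >= 10 even at p 0.1 -> easy
  # tile 2: max full depth 9 -> difficult
  # tile 3: half covered in full, shallow at p 0.1 -> intermediate
  dfull <- c(rep(30L, 95L), rep(0L, 5L), rep(9L, 100L),
             rep(c(12L, 3L), each = 50L))
  dp01 <- c(rep(10L, 95L), rep(0L, 5L), rep(1L, 100L), rep(1L, 100L))
  mk <- function(d) structure(list(target = target, depth = d),
                              class = "depth_profile")
  cls <- classify_tiles(mk(dfull), mk(dp01), tiles)
  expect_equal(cls$class, c("easy", "difficult", "intermediate"))
  expect_equal(cls$well_covered, c(TRUE, FALSE, FALSE))
  # difficult and easy are mutually exclusive by construction of the rules
  expect_false(any(cls$class == "difficult" & cls$well_covered))

  # "at least 90%" is literal for short tiles: 4/5 bases is not enough
  t5 <- merge_intervals(genomic_intervals("chr1", 0, 5))
  tl5 <- tile_targets(t5, 100L)
  mk5 <- function(d) structure(list(target = t5, depth = d),
                               class = "depth_profile")
  c45 <- classify_tiles(mk5(c(10L, 10L, 10L, 10L, 0L)), mk5(rep(0L, 5L)), tl5)
  expect_false(c45$well_covered)
  c55 <- classify_tiles(mk5(rep(10L, 5L)), mk5(rep(0L, 5L)), tl5)
  expect_true(c55$well_covered)
})

test_that("tile_gc excludes ambiguous bases from both terms", {
  ref <- c(chr1 = "GGCCATATGANT")
  tiles <- data.table(chrom = "chr1", start = c(0L, 4L, 8L), end = c(4L, 8L, 12L))
  expect_equal(tile_gc(tiles, ref), c(1.0, 0.0, 1 / 3))
})

test_that("tile_sharing matches brute-force set intersection", {
  cl <- rbind(
    data.table(sample_id = "s1", tile_id = c("t1", "t2", "t3"), class = "difficult"),
    data.table(sample_id = "s2", tile_id = c("t2", "t3", "t4"), class = "difficult"),
    data.table(sample_id = "s3", tile_id = "t9", class = "easy"))
  sh <- tile_sharing(cl, "difficult")
  expect_equal(sh$matrix["s1", "s2"], 2 / 3)
  expect_equal(sh$matrix["s2", "s1"], 2 / 3)
  expect_true(is.na(sh$matrix["s3", "s1"]))  # s3 has no difficult tiles

  # identical and disjoint classifications
  same <- rbind(data.table(sample_id = "a", tile_id = c("x", "y"), class = "difficult"),
                data.table(sample_id = "b", tile_id = c("x", "y"), class = "difficult"))
  expect_equal(tile_sharing(same, "difficult")$mean, 1)
  disj <- rbind(data.table(sample_id = "a", tile_id = "x", class = "difficult"),
                data.table(sample_id = "b", tile_id = "y", class = "difficult"))
  expect_equal(tile_sharing(disj, "difficult")$mean, 0)

  # random sets vs plain loops
  set.seed(14)
  rand <- rbindlist(lapply(sprintf("s%d", 1:4), function(s)
    data.table(sample_id = s,
               tile_id = sample(sprintf("t%02d", 1:30), 12L), class = "difficult")))
  sh <- tile_sharing(rand, "difficult")
  for (a in sprintf("s%d", 1:4)) for (b in sprintf("s%d", 1:4)) {
    ta <- rand[sample_id == a, tile_id]; tb <- rand[sample_id == b, tile_id]
    expect_equal(sh$matrix[a, b], length(intersect(ta, tb)) / length(ta))
  }
})

test_that("covered_target_sets unions per method and intersects across methods", {
  cov <- rbind(
    data.table(sample_id = "s1", method = "m1", tile_id = c("t1", "t2"),
               covered = TRUE),
    data.table(sample_id = "s2", method = "m1", tile_id = "t3", covered = FALSE),
    data.table(sample_id = "s3", method = "m2", tile_id = c("t2", "t3"),
               covered = TRUE))
  r <- covered_target_sets(cov)
  expect_equal(r$per_method$m1, c("t1", "t2"))
  expect_equal(r$per_method$m2, c("t2", "t3"))
  expect_equal(r$intersection, "t2")
  expect_error(covered_target_sets(cov[method == "none"]),
               class = "senscall_input_error")
})

test_that("capture-failure flagging uses median - k * MAD", {
  counts <- c(s1 = 100, s2 = 98, s3 = 99, s4 = 40)
  expect_equal(flag_capture_failures(counts), "s4")
  expect_equal(flag_capture_failures(c(a = 5, b = 5, c = 5)), character(0))
  expect_equal(flag_capture_failures(counts, k_mad = Inf), character(0))
  expect_error(flag_capture_failures(c(a = 1, b = 2)),
               class = "senscall_input_error")
})

test_that("total sensitivity is monotone under pointwise depth increase", {
  target <- merge_intervals(genomic_intervals("chr1", 0, 300))
  tab <- random_table(seed = 20L)  # sorted -> monotone table
  set.seed(21)
  d1 <- sample(0:40, 300L, TRUE)
  d2 <- d1 + sample(0:5, 300L, TRUE)
  mk <- function(d) structure(list(target = target, depth = d),
                              class = "depth_profile")
  t1 <- total_sensitivity(mk(d1), tab)
  t2 <- total_sensitivity(mk(d2), tab)
  expect_true(all(t2 >= t1))
})
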