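# Applying a calibration table to depth data: per-base sensitivity tracks,
# region aggregation, total sensitivity, required-depth estimation, and the
# easy/difficult tile analysis.

# sensitivity lookup vector indexed by depth 0..max; depth 0 is always 0
# (no call is possible with no reads), higher depths are clamped to the top
# row. Undefined (NA) rows at depths that actually occur are an error.
table_lookup <- function(curves, gt_class, depths) {
  tab <- as.data.table(curves)
  tab <- tab[genotype == gt_class]
  if (nrow(tab) == 0L) stop_input("calibration table has no '%s' rows", gt_class)
  setorder(tab, depth)
  maxd <- max(tab$depth)
  lut <- rep(NA_real_, maxd + 1L)
  lut[tab$depth + 1L] <- tab$sensitivity
  lut[1L] <- 0
  d <- pmin(depths, maxd)
  out <- lut[d + 1L]
  if (anyNA(out)) {
    miss <- sort(unique(d[is.na(out)]))
    stop_input("calibration table undefined at occurring depth(s): %s",
               paste(head(miss, 10L), collapse = ", "))
  }
  out
}

#' Per-base sensitivity track
#'
#' Maps each targeted position's depth through the calibration table,
#' separately for the heterozygous and homozygous genotype classes. Depth 0
#' maps to sensitivity 0; depths above the table maximum are clamped to the
#' top row.
#'
#' @param profile a `depth_profile`.
#' @param curves long-form calibration table (see [read_recall_table()]).
#' @return a `sensitivity_track`: list with `target`, `het`, `hom` (numeric
#'   vectors over targeted positions in profile order) and `depth`.
#' @export
per_base_sensitivity <- function(profile, curves) {
  structure(list(target = profile$target,
                 depth = profile$depth,
                 het = table_lookup(curves, "het", profile$depth),
                 hom = table_lookup(curves, "hom", profile$depth)),
            class = "sensitivity_track")
}

#' Write a sensitivity track as bedGraph
#'
#' @param track a `sensitivity_track`.
#' @param path output path.
#' @param genotype which class to export.
#' @return the path, invisibly.
#' @export
write_track_bedgraph <- function(track, path, genotype = c("het", "hom")) {
  genotype <- match.arg(genotype)
  prof <- structure(list(target = track$target, depth = track[[genotype]]),
                    class = "depth_profile")
  write_bedgraph(prof, path)
}

#' Summarize a sensitivity track over labeled regions
#'
#' Per region: length (overlapping the track's target), mean and min
#' sensitivity per genotype class, the fraction of bases below
#' `low_threshold`, and the expected missed-variant fraction
#' (1 - mean sensitivity). The length-weighted mean over a partition of the
#' target reconstitutes the whole-target mean exactly. Regions reaching
#' outside the target are clipped; regions with no targeted base get `NA`
#' values.
#'
#' @param track a `sensitivity_track`.
#' @param regions interval table with a `label` column (e.g. from
#'   [read_bed()]).
#' @param low_threshold sensitivity below which a base counts as poorly
#'   screened (default 0.95).
#' @return `data.table`, one row per region.
#' @export
aggregate_regions <- function(track, regions, low_threshold = 0.95) {
  reg <- as.data.table(regions)
  if (!"label" %in% names(reg)) reg[, label := sprintf("region%03d", .I)]
  validate_intervals(reg)
  iv <- copy(track$target$intervals)
  iv[, idx_off := cumsum(c(0L, head(end - start, -1L)))]
  iv2 <- iv[, .(chrom, s = start, e = end - 1L, idx_off)]
  setkey(iv2, chrom, s, e)
  reg[, rid := .I]
  reg2 <- reg[, .(chrom, s = start, e = end - 1L, xend = end, rid)]
  ov <- foverlaps(setkey(reg2, chrom, s, e), iv2, nomatch = NULL)
  out <- reg[, .(rid, label, chrom, start, end)]
  stats_list <- vector("list", nrow(reg))
  for (k in seq_len(nrow(reg))) {
    rows <- ov[rid == k]
    if (nrow(rows) == 0L) {
      stats_list[[k]] <- data.table(length = 0L, het_mean = NA_real_,
                                    het_min = NA_real_, hom_mean = NA_real_,
                                    hom_min = NA_real_, frac_below = NA_real_,
                                    het_missed = NA_real_, hom_missed = NA_real_)
      next
    }
    idx <- unlist(lapply(seq_len(nrow(rows)), function(j) {
      a <- max(rows$i.s[j], rows$s[j])          # clipped genomic [a, b)
      b <- min(rows$xend[j], rows$e[j] + 1L)
      (rows$idx_off[j] + (a - rows$s[j]) + 1L):(rows$idx_off[j] + (b - rows$s[j]))
    }))
    het <- track$het[idx]; hom <- track$hom[idx]
    stats_list[[k]] <- data.table(
      length = length(idx),
      het_mean = mean(het), het_min = min(het),
      hom_mean = mean(hom), hom_min = min(hom),
      frac_below = mean(het < low_threshold),
      het_missed = 1 - mean(het), hom_missed = 1 - mean(hom))
  }
  cbind(out, rbindlist(stats_list))[, rid := NULL][]
}

#' Total (exome-wide) detection sensitivity
#'
#' The depth-distribution-weighted mean sensitivity over the whole target:
#' the mean over targeted positions of the calibrated sensitivity at each
#' position's depth, per genotype class. Equals the mean of the per-base
#' sensitivity track.
#'
#' @param profile a `depth_profile`.
#' @param curves long-form calibration table.
#' @return named numeric vector `c(het = ..., hom = ...)`.
#' @export
total_sensitivity <- function(profile, curves) {
  if (length(profile$depth) == 0L) stop_input("empty depth profile")
  c(het = mean(table_lookup(curves, "het", profile$depth)),
    hom = mean(table_lookup(curves, "hom", profile$depth)))
}

#' Mean on-target depth required for a total-sensitivity level
#'
#' Given (mean depth, total sensitivity) points from a down-sampling series,
#' fits an isotonic (monotone non-decreasing) regression of sensitivity on
#' depth and linearly interpolates the first crossing of each requested
#' level. Levels above the maximum achieved sensitivity are reported as
#' unattained (`NA` depth).
#'
#' @param depths mean on-target depths (>= 2 points).
#' @param sens matching total sensitivities.
#' @param levels target sensitivity levels.
#' @return `data.table`: `level`, `depth`, `attained`.
#' @export
required_mean_depth <- function(depths, sens, levels = c(0.80, 0.90, 0.95)) {
  if (length(depths) < 2L || length(depths) != length(sens))
    stop_input("need >= 2 (depth, sensitivity) points of equal length")
  o <- order(depths)
  x <- depths[o]
  y <- isoreg(x, sens[o])$yf
  out <- data.table(level = levels, depth = NA_real_, attained = FALSE)
  for (i in seq_along(levels)) {
    lv <- levels[i]
    j <- which(y >= lv)
    if (length(j) == 0L) next
    j <- j[1L]
    if (j == 1L || y[j] == lv) {
      d <- x[j]
    } else {
      # linear interpolation between the bracketing points
      d <- x[j - 1L] + (lv - y[j - 1L]) / (y[j] - y[j - 1L]) * (x[j] - x[j - 1L])
    }
    out[i, `:=`(depth = d, attained = TRUE)]
  }
  out[]
}

#' Classify target tiles as difficult, easy or intermediate
#'
#' A base is well-covered at depth >= 10; a tile is well-covered when at
#' least 90% of its bases are. A tile is *difficult* when it has no
#' well-covered base in the full alignment, *easy* when it is well-covered
#' even in the p = 0.1 down-sampled alignment, otherwise *intermediate*.
#' The `well_covered` flag refers to the full alignment.
#'
#' @param full_profile depth profile of the full alignment.
#' @param p01_profile depth profile of the p = 0.1 down-sampled alignment
#'   (same target).
#' @param tiles tile table from [tile_targets()] on the same target.
#' @param min_depth well-covered depth cutoff (default 10).
#' @param frac well-covered base fraction cutoff (default 0.9).
#' @return `data.table`: tile columns plus `well_covered` and `class`.
#' @export
classify_tiles <- function(full_profile, p01_profile, tiles,
                           min_depth = 10L, frac = 0.9) {
  tl <- as.data.table(tiles)
  W <- target_width(full_profile$target)
  widths <- tl$end - tl$start
  if (sum(widths) != W || length(p01_profile$depth) != W)
    stop_contract("tiles and profiles must partition the same target")
  tix <- rep(seq_len(nrow(tl)), widths)
  dt <- data.table(tix = tix, dfull = full_profile$depth,
                   dp01 = p01_profile$depth)
  st <- dt[, .(frac_full = mean(dfull >= min_depth),
               any_full = any(dfull >= min_depth),
               frac_p01 = mean(dp01 >= min_depth)), by = tix]
  out <- copy(tl)
  out[, well_covered := st$frac_full >= frac]
  out[, class := fifelse(!st$any_full, "difficult",
                  fifelse(st$frac_p01 >= frac, "easy", "intermediate"))]
  out[]
}

#' G+C fraction of tiles
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; ambiguous bases are excluded from both
#' numerator and denominator. `NaN` for tiles with no unambiguous base.
#'
#' @param tiles tile (or any interval) table.
#' @param reference named character vector of sequences.
#' @return numeric vector of G+C fractions.
#' @export
tile_gc <- function(tiles, reference) {
  tl <- as.data.table(tiles)
  s <- toupper(substring(reference[tl$chrom], tl$start + 1L, tl$end))
  gc <- nchar(gsub("[^GC]", "", s))
  acgt <- nchar(gsub("[^ACGT]", "", s))
  unname(gc / acgt)
}

#' Pairwise tile-class sharing between samples
#'
#' For each ordered pair of samples (a, b) the fraction of a's tiles of the
#' requested class that are also in b's: `|A intersect B| / |A|`. Pairs
#' where a has no tile in the class are skipped (NA).
#'
#' @param classifications `data.table` with `sample_id`, `tile_id`, `class`
#'   (rbind of per-sample [classify_tiles()] outputs with a `sample_id`
#'   column added).
#' @param class_label class to analyse (e.g. `"difficult"`).
#' @return list: `matrix` (ordered-pair shared fractions), `mean`, `sd`
#'   over the defined off-diagonal pairs.
#' @export
tile_sharing <- function(classifications, class_label = "difficult") {
  cl <- as.data.table(classifications)
  if (uniqueN(cl$sample_id) < 2L) stop_input("need >= 2 samples")
  sets <- cl[class == class_label, .(tiles = list(unique(tile_id))), by = sample_id]
  samples <- sort(unique(cl$sample_id))
  m <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  get <- function(s) {
    i <- match(s, sets$sample_id)
    if (is.na(i)) character(0) else sets$tiles[[i]]
  }
  for (a in samples) for (b in samples) {
    ta <- get(a)
    if (length(ta) == 0L) next  # skipped, stays NA
    m[a, b] <- length(intersect(ta, get(b))) / length(ta)
  }
  off <- m[row(m) != col(m)]
  list(matrix = m, mean = mean(off, na.rm = TRUE),
       sd = sd(off, na.rm = TRUE))
}

#' Per-method covered target sets and their intersection
#'
#' A method's covered set is the union over its samples of tiles touched by
#' at least one read; the across-method intersection defines the common
#' target used to compare capture methods.
#'
#' @param coverage `data.table` with `sample_id`, `method`, `tile_id`,
#'   `covered` (logical: any read on the tile).
#' @return list: `per_method` (named list of tile-id vectors),
#'   `intersection` (tile ids covered by every method).
#' @export
covered_target_sets <- function(coverage) {
  cov <- as.data.table(coverage)
  if (nrow(cov) == 0L) stop_input("empty method group")
  methods <- unique(cov$method)
  per <- lapply(methods, function(m) {
    sub <- cov[method == m]
    if (nrow(sub) == 0L) stop_input("empty method group '%s'", m)
    sort(unique(sub[covered == TRUE, tile_id]))
  })
  names(per) <- methods
  list(per_method = per, intersection = Reduce(intersect, per))
}

#' Flag samples with partial capture failure
#'
#' Samples whose well-covered tile count falls below
#' `median - k_mad * MAD` of the cohort indicate failed capture and should
#' be excluded from summary statistics.
#'
#' @param counts named numeric vector of well-covered tile counts per
#'   sample (>= 3 samples).
#' @param k_mad multiplier on the (scaled) median absolute deviation.
#' @return character vector of flagged sample names.
#' @export
flag_capture_failures <- function(counts, k_mad = 3) {
  if (length(counts) < 3L) stop_input("need >= 3 samples")
  med <- median(counts)
  delta <- k_mad * mad(counts)
  if (is.nan(delta)) delta <- Inf  # k_mad = Inf with MAD 0: flag nothing
  names(counts)[counts < med - delta]
}
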