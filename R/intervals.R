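#' Construct a table of genomic intervals
#'
#' Intervals are 0-based half-open `[start, end)`, the internal convention
#' throughout the package. Conversion to 1-based coordinates happens only in
#' the VCF reader/writer.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `start < end` required.
#' @param label optional character vector of interval labels (e.g. gene names).
#' @return a `data.table` with columns `chrom`, `start`, `end` (and `label`
#'   if given).
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL) {
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end))
  if (!is.null(label)) dt[, label := as.character(label)]
  validate_intervals(dt)
  dt[]
}

validate_intervals <- function(dt) {
  if (!all(c("chrom", "start", "end") %in% names(dt)))
    stop_input("intervals need chrom/start/end columns")
  if (nrow(dt) == 0L) return(invisible(dt))
  if (anyNA(dt$start) || anyNA(dt$end) || anyNA(dt$chrom))
    stop_input("intervals contain missing values")
  if (any(!nzchar(dt$chrom)))
    stop_input("interval with empty chromosome name")
  bad <- which(dt$start >= dt$end)
  if (length(bad))
    stop_input("interval with start >= end at row %d (%s:%d-%d)",
               bad[1], dt$chrom[bad[1]], dt$start[bad[1]], dt$end[bad[1]])
  invisible(dt)
}

#' Merge intervals into a target set
#'
#' Produces the minimal sorted set of non-overlapping, non-abutting intervals
#' covering the positional union of the input, so that every targeted position
#' is represented exactly once. This mirrors how overlapping exon annotations
#' are collapsed into a capture target definition.
#'
#' @param intervals a data.frame/data.table with `chrom`, `start`, `end`
#'   (0-based half-open); may be unsorted, overlapping or abutting.
#' @param label name for the resulting target set.
#' @return a `target_set`: list with elements `intervals` (sorted
#'   `data.table`) and `label`.
#' @examples
#' ts <- merge_intervals(genomic_intervals("chr1", c(0, 5), c(10, 15)))
#' ts$intervals  # chr1 0 15
#' @export
merge_intervals <- function(intervals, label = "target") {
  dt <- as.data.table(intervals)[, .(chrom = as.character(chrom),
                                     start = as.integer(start),
                                     end = as.integer(end))]
  validate_intervals(dt)
  if (nrow(dt)) {
    setkey(dt, chrom, start, end)
    # abutting intervals (end == next start) are merged too
    dt[, grp := cumsum(c(1L, as.integer(
      chrom[-1] != chrom[-.N] | start[-1] > cummax_by(end, chrom)[-.N])))]
    dt <- dt[, .(chrom = chrom[1], start = start[1], end = max(end)), by = grp]
    dt[, grp := NULL]
  }
  structure(list(intervals = dt[], label = label), class = "target_set")
}

# running max of end within chrom blocks (input sorted by chrom, start)
cummax_by <- function(x, g) {
  ave_res <- stats::ave(x, g, FUN = cummax)
  as.integer(ave_res)
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set '%s': %d intervals, %d bp on %d chrom(s)\n",
              x$label, nrow(x$intervals), target_width(x),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Total targeted length of a target set
#' @param target a `target_set`.
#' @return integer, total covered bases.
#' @export
target_width <- function(target) {
  stopifnot(inherits(target, "target_set"))
  sum(target$intervals$end - target$intervals$start)
}

#' Split target intervals into non-overlapping tiles
#'
#' Each target interval of length L is split into `floor(L / max_len)` tiles
#' of `max_len` bases anchored at the interval start, plus one short remainder
#' tile at the right edge when `L %% max_len > 0`. Tiles partition their
#' parent interval exactly and never cross interval boundaries.
#'
#' @param target a `target_set`.
#' @param max_len maximum tile length in bp (default 100).
#' @return `data.table` with columns `chrom`, `start`, `end`, `parent_id`
#'   (row index of the source interval), `tile_index` (ordinal within parent)
#'   and `tile_id` (globally unique string).
#' @export
tile_targets <- function(target, max_len = 100L) {
  stopifnot(inherits(target, "target_set"))
  max_len <- as.integer(max_len)
  if (is.na(max_len) || max_len < 1L) stop_input("max_len must be >= 1")
  iv <- target$intervals
  if (nrow(iv) == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      parent_id = integer(), tile_index = integer(),
                      tile_id = character()))
  lens <- iv$end - iv$start
  ntiles <- (lens + max_len - 1L) %/% max_len
  parent_id <- rep(seq_len(nrow(iv)), ntiles)
  tile_index <- sequence(ntiles)
  start <- iv$start[parent_id] + (tile_index - 1L) * max_len
  end <- pmin(start + max_len, iv$end[parent_id])
  dt <- data.table(chrom = iv$chrom[parent_id], start = start, end = end,
                   parent_id = parent_id, tile_index = tile_index)
  dt[, tile_id := sprintf("%s:%d-%d", chrom, start, end)]
  dt[]
}

#' Restrict a target set to the positions of another
#'
#' @param target,other `target_set` objects.
#' @return a new `target_set` covering the positional intersection.
#' @export
intersect_targets <- function(target, other) {
  a <- copy(target$intervals); b <- copy(other$intervals)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(merge_intervals(a[0], label = target$label))
  b2 <- b[, .(chrom, s = start, e = end - 1L, xend = end)]
  setkey(b2, chrom, s, e)
  a2 <- a[, .(chrom, s = start, e = end - 1L, xend = end)]
  ov <- foverlaps(setkey(a2, chrom, s, e), b2, nomatch = NULL)
  if (nrow(ov) == 0L) return(merge_intervals(a[0], label = target$label))
  merged <- ov[, .(chrom, start = pmax(s, i.s), end = pmin(xend, i.xend))]
  merge_intervals(merged[start < end], label = target$label)
}
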