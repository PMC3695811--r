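#' Per-base read depth over a target set
#'
#' Depth at a targeted position is the number of reads whose aligned
#' reference span overlaps the position, counting M and D CIGAR operations as
#' covering: a read aligned with a deletion (gap) across a position still
#' counts towards its depth. Insertions and soft clips consume no reference
#' and never contribute. Off-target portions of reads are not recorded; reads
#' on chromosomes absent from the target are skipped and counted in
#' `attr(profile, "n_skipped_chrom")`.
#'
#' @param reads an aligned-read table (see [aligned_reads()]); order is
#'   irrelevant.
#' @param target a `target_set`.
#' @return a `depth_profile`: list with `target` and `depth`, an integer
#'   vector holding the depth of every targeted position in target order.
#' @export
compute_depth_profile <- function(reads, target) {
  stopifnot(inherits(target, "target_set"))
  W <- target_width(target)
  if (W == 0L) stop_input("empty target set")
  iv <- profile_offsets_raw(target)
  depth <- integer(W)
  n_skip <- 0L
  if (nrow(reads)) {
    r <- as.data.table(reads)[, .(chrom, start = pos,
                                  end = pos + cigar_ref_span(cigar))]
    n_skip <- sum(!r$chrom %in% iv$chrom)
    r <- r[end > start]
    if (nrow(r)) {
      # foverlaps treats intervals as closed; join on inclusive ends
      iv2 <- iv[, .(chrom, s = start, e = end - 1L, idx_off)]
      setkey(iv2, chrom, s, e)
      r2 <- r[, .(chrom, s = start, e = end - 1L, xend = end)]
      setkey(r2, chrom, s, e)
      ov <- foverlaps(r2, iv2, nomatch = NULL)
      if (nrow(ov)) {
        a <- pmax(ov$i.s, ov$s)            # clipped genomic [a, b)
        b <- pmin(ov$xend, ov$e + 1L)
        i0 <- ov$idx_off + (a - ov$s) + 1L
        i1 <- ov$idx_off + (b - ov$s) + 1L  # exclusive
        inc <- tabulate(i0, nbins = W + 1L) - tabulate(i1, nbins = W + 1L)
        depth <- cumsum(inc)[seq_len(W)]
      }
    }
  }
  structure(list(target = target, depth = as.integer(depth),
                 n_skipped_chrom = n_skip),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile over %d bp: mean %.2f, max %d\n",
              length(x$depth), mean(x$depth), max(x$depth)))
  invisible(x)
}

# target intervals with the cumulative index offset of each interval in the
# profile vector
profile_offsets_raw <- function(target) {
  iv <- copy(target$intervals)
  iv[, idx_off := cumsum(c(0L, head(end - start, -1L)))]
  iv
}

profile_offsets <- function(profile) profile_offsets_raw(profile$target)

#' Enumerate targeted positions
#'
#' @param profile a `depth_profile` (or `target_set` via `target`).
#' @return `data.table` with `chrom`, `pos` (0-based) and `depth` for every
#'   targeted position, in profile order.
#' @export
profile_positions <- function(profile) {
  iv <- profile$target$intervals
  lens <- iv$end - iv$start
  data.table(chrom = rep(iv$chrom, lens),
             pos = unlist(lapply(seq_len(nrow(iv)),
                                 function(i) seq.int(iv$start[i], iv$end[i] - 1L))),
             depth = profile$depth)
}

#' Depth at specific positions
#'
#' @param profile a `depth_profile`.
#' @param chrom,pos vectors of positions (0-based).
#' @return integer vector; `NA` for positions outside the target.
#' @export
depth_at <- function(profile, chrom, pos) {
  iv2 <- profile_offsets(profile)[, .(chrom, s = start, e = end - 1L, idx_off)]
  setkey(iv2, chrom, s, e)
  q <- data.table(chrom = as.character(chrom), s = as.integer(pos),
                  e = as.integer(pos), qid = seq_along(pos))
  setkey(q, chrom, s, e)
  ov <- foverlaps(q, iv2, nomatch = NA)
  out <- rep(NA_integer_, nrow(q))
  hit <- !is.na(ov$idx_off)
  out[ov$qid[hit]] <- profile$depth[ov$idx_off[hit] + (ov$i.s[hit] - ov$s[hit]) + 1L]
  out
}

#' Mean on-target read depth
#'
#' Arithmetic mean of per-base depth over all targeted positions (bases
#' aligned to the target divided by target size).
#'
#' @param profile a `depth_profile`.
#' @return non-negative numeric scalar.
#' @export
mean_on_target_depth <- function(profile) {
  if (length(profile$depth) == 0L) stop_input("empty depth profile")
  mean(profile$depth)
}

#' Depth profile to/from bedGraph
#'
#' bedGraph rows are runs of constant depth (`chrom start end depth`,
#' 0-based half-open). `read_bedgraph()` fills the given target's positions
#' from the file; targeted positions missing from the file get depth 0.
#'
#' @param profile a `depth_profile`.
#' @param path file path.
#' @param target a `target_set` the bedGraph is read against.
#' @return `write_bedgraph()` the path, invisibly; `read_bedgraph()` a
#'   `depth_profile`.
#' @export
write_bedgraph <- function(profile, path) {
  pp <- profile_positions(profile)
  pp[, run := rleid(chrom, depth, cumsum(c(0L, diff(pos) != 1L)))]
  runs <- pp[, .(chrom = chrom[1], start = pos[1], end = pos[.N] + 1L,
                 depth = depth[1]), by = run][, run := NULL]
  fwrite(runs, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, target) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "depth"))
  prof <- structure(list(target = target,
                         depth = numeric(target_width(target)),
                         n_skipped_chrom = 0L),
                    class = "depth_profile")
  if (nrow(dt) == 0L) return(prof)
  iv2 <- profile_offsets_raw(target)[, .(chrom, s = start, e = end - 1L, idx_off)]
  setkey(iv2, chrom, s, e)
  r2 <- dt[, .(chrom, s = start, e = end - 1L, xend = end, depth)]
  setkey(r2, chrom, s, e)
  ov <- foverlaps(r2, iv2, nomatch = NULL)
  for (k in seq_len(nrow(ov))) {
    a <- max(ov$i.s[k], ov$s[k]); b <- min(ov$xend[k], ov$e[k] + 1L)
    idx <- (ov$idx_off[k] + (a - ov$s[k]) + 1L):(ov$idx_off[k] + (b - ov$s[k]))
    prof$depth[idx] <- ov$depth[k]
  }
  if (all(prof$depth == round(prof$depth)))
    prof$depth <- as.integer(round(prof$depth))
  prof
}
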