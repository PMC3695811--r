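#' Read alignments from a SAM text file
#'
#' Minimal SAM parser for coordinate data: keeps name, flag, chrom, 0-based
#' position, mapping quality, CIGAR, bases and qualities. Unmapped (0x4),
#' secondary (0x100) and supplementary (0x800) records are skipped; their
#' count is in `attr(reads, "n_skipped")`. The sample label is taken from the
#' first `@RG SM:` header tag when present.
#'
#' @param path SAM file path.
#' @param sample_id fallback sample label when no `@RG` header exists.
#' @return an aligned-read `data.table` (see [aligned_reads()]).
#' @export
read_sam <- function(path, sample_id = "sample") {
  lines <- readLines(path)
  hdr <- startsWith(lines, "@")
  rg <- grep("^@RG\t", lines[hdr], value = TRUE)
  if (length(rg)) {
    sm <- regmatches(rg[1], regexpr("SM:[^\t]+", rg[1]))
    if (length(sm)) sample_id <- sub("^SM:", "", sm)
  }
  body <- lines[!hdr]
  lineno <- which(!hdr)
  if (length(body) == 0L) {
    return(aligned_reads(character(), character(), integer(), character(),
                         character(), character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop_input("malformed SAM line %d: fewer than 11 fields", lineno[which(nf < 11L)[1]])
  m <- matrix(unlist(lapply(fields, `[`, 1:11)), ncol = 11L, byrow = TRUE)
  flag <- suppressWarnings(as.integer(m[, 2]))
  pos1 <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(flag) || anyNA(pos1))
    stop_input("malformed SAM line %d: non-numeric FLAG or POS",
               lineno[which(is.na(flag) | is.na(pos1))[1]])
  skip <- bitwAnd(flag, 0x4L) != 0L | bitwAnd(flag, 0x100L) != 0L |
    bitwAnd(flag, 0x800L) != 0L
  keep <- !skip
  dt <- aligned_reads(name = m[keep, 1], chrom = m[keep, 3],
                      pos = pos1[keep] - 1L, cigar = m[keep, 6],
                      bases = m[keep, 10], quals = m[keep, 11],
                      flag = flag[keep],
                      mapq = suppressWarnings(as.integer(m[keep, 5])),
                      sample_id = sample_id)
  setattr(dt, "n_skipped", sum(skip))
  dt
}

#' Write alignments to a SAM text file
#'
#' Emits an `@HD`/`@SQ` header (reference lengths from `seqlens`, or inferred
#' from the rightmost aligned base per chromosome) and one record per read.
#' Mate fields are filled for paired reads sharing a name.
#'
#' @param reads aligned-read table.
#' @param path output path.
#' @param seqlens optional named integer vector of reference lengths.
#' @return the path, invisibly.
#' @export
write_sam <- function(reads, path, seqlens = NULL) {
  r <- as.data.table(reads)
  if (nrow(r)) {
    r[, refspan := cigar_ref_span(cigar)]
    if (is.null(seqlens))
      seqlens <- r[, .(len = max(pos + refspan)), by = chrom][, setNames(len, chrom)]
  } else if (is.null(seqlens)) {
    seqlens <- integer(0)
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), as.integer(seqlens)))
  if (nrow(r))
    hdr <- c(hdr, sprintf("@RG\tID:rg1\tSM:%s", r$sample_id[1]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(r) == 0L) return(invisible(path))
  setorder(r, chrom, pos)
  # mate coordinates for paired reads (pairs identified by shared name)
  r[, `:=`(rnext = "*", pnext = 0L, tlen = 0L)]
  if (any(r$is_paired)) {
    idx <- which(r$is_paired)
    pd <- data.table(i = idx, name = r$name[idx], pos = r$pos[idx])
    pd <- pd[, if (.N == 2L) .(i = i, mpos = rev(pos)) else NULL, by = name]
    if (nrow(pd)) r[pd$i, `:=`(rnext = "=", pnext = pd$mpos + 1L)]
  }
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  r$name, r$flag, r$chrom, r$pos + 1L, r$mapq, r$cigar,
                  r$rnext, r$pnext, r$tlen, r$bases, r$quals)
  writeLines(recs, con)
  invisible(path)
}
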