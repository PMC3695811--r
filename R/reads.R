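#' Construct an aligned-read table
#'
#' The minimal alignment representation used throughout: enough to compute
#' depth and pileups. CIGAR strings are restricted to the operations M
#' (match/mismatch), I (insertion), D (deletion) and S (soft clip). Base
#' qualities are stored SAM-style as Phred+33 characters.
#'
#' @param name read name; mates of a pair share the name.
#' @param chrom reference name.
#' @param pos 0-based leftmost aligned position.
#' @param cigar CIGAR string (ops in M, I, D, S).
#' @param bases read sequence.
#' @param quals Phred+33 quality string, same length as `bases`.
#' @param flag SAM flag (default 0; pairing is taken from bit 0x1).
#' @param mapq mapping quality (default 60).
#' @param sample_id sample label.
#' @return a `data.table` with one row per read and an `is_paired` column.
#' @export
aligned_reads <- function(name, chrom, pos, cigar, bases, quals,
                          flag = 0L, mapq = 60L, sample_id = "sample") {
  dt <- data.table(name = as.character(name), flag = as.integer(flag),
                   chrom = as.character(chrom), pos = as.integer(pos),
                   mapq = as.integer(mapq), cigar = as.character(cigar),
                   bases = as.character(bases), quals = as.character(quals),
                   sample_id = as.character(sample_id))
  dt[, is_paired := bitwAnd(flag, 1L) != 0L]
  validate_reads(dt)
  dt[]
}

validate_reads <- function(dt) {
  if (nrow(dt) == 0L) return(invisible(dt))
  qlen <- cigar_query_len(dt$cigar)
  bad <- which(qlen != nchar(dt$bases) | nchar(dt$bases) != nchar(dt$quals))
  if (length(bad))
    stop_input("read '%s': CIGAR query length, sequence and quality lengths disagree",
               dt$name[bad[1]])
  if (any(dt$pos < 0L)) stop_input("negative alignment position")
  invisible(dt)
}

# ---- CIGAR arithmetic -------------------------------------------------------

parse_cigar_one <- function(cig) {
  m <- gregexpr("(\\d+)([MIDS])", cig, perl = TRUE)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cig))
    stop_input("malformed CIGAR '%s'", cig)
  toks <- regmatches(cig, gregexpr("\\d+[MIDS]", cig))[[1]]
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

# vectorized over a cigar vector via a per-unique-string cache
cigar_summarise <- function(cigars, ops_keep) {
  u <- unique(cigars)
  vals <- vapply(u, function(cg) {
    p <- parse_cigar_one(cg)
    sum(p$len[p$op %in% ops_keep])
  }, integer(1))
  unname(vals[match(cigars, u)])
}

#' CIGAR length helpers
#'
#' `cigar_query_len()` is the number of read bases consumed (M + I + S);
#' `cigar_ref_span()` is the reference span (M + D).
#'
#' @param cigars character vector of CIGAR strings.
#' @return integer vector.
#' @export
cigar_query_len <- function(cigars) cigar_summarise(cigars, c("M", "I", "S"))

#' @rdname cigar_query_len
#' @export
cigar_ref_span <- function(cigars) cigar_summarise(cigars, c("M", "D"))

# For one read, the query offsets (1-based) of reference positions covered by
# M ops, as a data.table(refpos, qoff). D positions consume reference but have
# no query base; I and S consume query only.
cigar_m_offsets <- function(cig, pos) {
  p <- parse_cigar_one(cig)
  refpos <- integer(0); qoff <- integer(0)
  rp <- pos; qp <- 1L
  for (i in seq_along(p$op)) {
    op <- p$op[i]; len <- p$len[i]
    if (op == "M") {
      refpos <- c(refpos, rp:(rp + len - 1L))
      qoff <- c(qoff, qp:(qp + len - 1L))
      rp <- rp + len; qp <- qp + len
    } else if (op == "D") {
      rp <- rp + len
    } else { # I or S
      qp <- qp + len
    }
  }
  list(refpos = refpos, qoff = qoff)
}
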