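# BED, VCF, FASTA text I/O. Internal coordinates are 0-based half-open;
# conversion to VCF's 1-based positions happens here and nowhere else.

#' Read/write BED3(+name) interval files
#'
#' @param path file path.
#' @return `read_bed()` a `data.table` of intervals (with `label` when a
#'   name column is present); `write_bed()` the path, invisibly.
#' @export
read_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3L) stop_input("BED file needs at least 3 columns: %s", path)
  out <- data.table(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]))
  if (ncol(dt) >= 4L && !all(is.na(dt[[4]]))) out[, label := as.character(dt[[4]])]
  validate_intervals(out)
  out[]
}

#' @rdname read_bed
#' @param intervals interval `data.table` or a `target_set`.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "target_set")) intervals <- intervals$intervals
  dt <- as.data.table(intervals)
  cols <- intersect(c("chrom", "start", "end", "label"), names(dt))
  fwrite(dt[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read known polymorphic sites from a VCF
#'
#' Multiallelic records are split into one biallelic site per ALT allele.
#' Records with symbolic or breakend ALT alleles are dropped; their count is
#' in `attr(sites, "n_symbolic")`. When sample columns carry GT fields, a
#' `gt_<sample>` column per sample reports the genotype relative to each split
#' allele: `"hom-ref"`, `"het"`, or `"hom"` (both alleles equal to that ALT).
#'
#' @param path VCF file path (plain text).
#' @return `data.table` with `chrom`, `pos` (0-based), `ref`, `alt` and
#'   optional `gt_*` columns.
#' @export
read_vcf_sites <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines, value = TRUE)
  samples <- character(0)
  if (length(hdr)) {
    cols <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
    if (length(cols) > 9L) samples <- cols[-(1:9)]
  }
  body <- lines[!startsWith(lines, "#")]
  empty <- data.table(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
  if (length(body) == 0L) {
    setattr(empty, "n_symbolic", 0L)
    return(empty)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L))
    stop_input("malformed VCF record (fewer than 8 fields) at data line %d",
               which(nf < 8L)[1])
  chrom <- vapply(fields, `[`, "", 1L)
  pos1 <- as.integer(vapply(fields, `[`, "", 2L))
  refs <- vapply(fields, `[`, "", 4L)
  alts <- vapply(fields, `[`, "", 5L)
  symbolic <- grepl("[][<>]", alts) | alts == "*"
  n_symbolic <- sum(symbolic)
  gt_idx <- NULL
  if (length(samples)) {
    fmt <- vapply(fields, function(f) if (length(f) >= 9L) f[9] else "", "")
    gt_idx <- lapply(strsplit(fmt, ":", fixed = TRUE), function(k) match("GT", k))
  }
  rows <- vector("list", length(body))
  for (i in which(!symbolic)) {
    alt_i <- strsplit(alts[i], ",", fixed = TRUE)[[1]]
    rec <- data.table(chrom = chrom[i], pos = pos1[i] - 1L, ref = refs[i],
                      alt = alt_i, allele_idx = seq_along(alt_i))
    if (length(samples) && !is.na(gt_idx[[i]])) {
      svals <- fields[[i]][-(1:9)]
      for (s in seq_along(samples)) {
        gt <- strsplit(svals[s], ":", fixed = TRUE)[[1]][gt_idx[[i]]]
        al <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
        cls <- vapply(rec$allele_idx, function(ai) {
          if (anyNA(al) || length(al) == 0L) return(NA_character_)
          hits <- sum(al == ai)
          if (hits == 2L) "hom" else if (hits == 1L) "het" else "hom-ref"
        }, character(1))
        rec[, (paste0("gt_", samples[s])) := cls]
      }
    }
    rows[[i]] <- rec
  }
  out <- rbindlist(rows[!vapply(rows, is.null, TRUE)], fill = TRUE)
  out[, allele_idx := NULL]
  if (n_symbolic)
    warning(sprintf("%d VCF record(s) with symbolic alleles dropped", n_symbolic))
  setattr(out, "n_symbolic", n_symbolic)
  out[]
}

#' Write variant calls to a single-sample VCF
#'
#' Emits GT (`0/1` het, `1/1` hom), DP (depth at site by the profile
#' definition) and GQ (rounded call quality).
#'
#' @param calls a variant-call `data.table` with `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `genotype` (`"het"`/`"hom"`), `qual`, `depth`.
#' @param sample sample name for the VCF column.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(calls, sample, path) {
  dt <- as.data.table(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=senscall",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth at site (M+D)\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  ), con)
  if (nrow(dt)) {
    setorder(dt, chrom, pos)
    gt <- ifelse(dt$genotype == "hom", "1/1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t.\tGT:DP:GQ\t%s:%d:%d",
                       dt$chrom, dt$pos + 1L, dt$ref, dt$alt,
                       pmin(dt$qual, 9999), gt, dt$depth,
                       as.integer(round(pmin(dt$qual, 9999)))), con)
  }
  invisible(path)
}

#' Read/write plain-text FASTA
#'
#' @param path file path.
#' @param width line width for writing.
#' @return `read_fasta()` a named character vector of sequences;
#'   `write_fasta()` the path, invisibly.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hd <- startsWith(lines, ">")
  if (!any(hd)) stop_input("no FASTA headers in %s", path)
  grp <- cumsum(hd)
  nm <- sub("^>", "", sub("\\s.*$", "", lines[hd]))
  seqs <- vapply(split(lines[!hd], factor(grp[!hd], levels = seq_along(nm))),
                 paste0, "", collapse = "")
  setNames(toupper(unname(seqs)), nm)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
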