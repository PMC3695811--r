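#' Build the gold-standard truth set
#'
#' A call from the full alignment enters the truth set when a known
#' polymorphic site matches it in position *and* alleles and the site lies
#' within the target regions. Position matches with mismatching alleles are
#' excluded and counted in `attr(truth, "n_allele_mismatch")`.
#'
#' @param full_calls variant calls from the full alignment.
#' @param panel known-site table (`chrom`, `pos`, `ref`, `alt`), e.g. from
#'   [read_vcf_sites()].
#' @param target a `target_set`.
#' @param qual_filter optional Phred threshold applied to the calls before
#'   matching.
#' @return `data.table` of truth records: `chrom`, `pos`, `ref`, `alt`,
#'   `genotype` (from the full-alignment call), `qual`.
#' @export
build_truth_set <- function(full_calls, panel, target, qual_filter = NULL) {
  calls <- as.data.table(full_calls)
  if (!is.null(qual_filter)) calls <- calls[qual >= qual_filter]
  pan <- as.data.table(panel)[, .(chrom = as.character(chrom),
                                  pos = as.integer(pos),
                                  ref = as.character(ref),
                                  alt = as.character(alt))]
  # restrict to target
  if (nrow(calls)) {
    iv2 <- copy(target$intervals)[, .(chrom, s = start, e = end - 1L)]
    setkey(iv2, chrom, s, e)
    q <- calls[, .(chrom, s = pos, e = pos, cid = .I)]
    ov <- foverlaps(setkey(q, chrom, s, e), iv2, nomatch = NULL)
    calls <- calls[sort(unique(ov$cid))]
  }
  pos_match <- merge(calls, pan[, .(chrom, pos, p_ref = ref, p_alt = alt)],
                     by = c("chrom", "pos"))
  allele_ok <- pos_match$ref == pos_match$p_ref & pos_match$alt == pos_match$p_alt
  truth <- pos_match[allele_ok, .(chrom, pos, ref, alt, genotype, qual)]
  setorder(truth, chrom, pos)
  setattr(truth, "n_allele_mismatch", sum(!allele_ok))
  truth[]
}

#' Classify down-sampled calls against the truth set
#'
#' Every truth record receives exactly one outcome per down-sampled
#' alignment: `TP` when a position+allele-matched call has the same genotype;
#' `PTP_het_called_hom` / `PTP_hom_called_het` when matched with the other
#' genotype (partial true positive); `FN` when no matched call exists. The
#' depth attached to each outcome is read from the down-sampled alignment's
#' depth profile at the site (so false negatives carry the depth at which
#' the variant was missed).
#'
#' @param truth truth set from [build_truth_set()] (or any table with
#'   `chrom`, `pos`, `ref`, `alt`, `genotype`).
#' @param ds_calls calls from the down-sampled alignment.
#' @param ds_depth `depth_profile` of the down-sampled alignment.
#' @param p the down-sampling probability (recorded, not used).
#' @param replicate_id replicate label.
#' @return `data.table`: `chrom`, `pos`, `true_genotype`, `outcome`,
#'   `depth_at_site`, `downsample_p`, `replicate_id`.
#' @export
classify_downsampled <- function(truth, ds_calls, ds_depth, p,
                                 replicate_id = 1L) {
  tr <- as.data.table(truth)[, .(chrom, pos, ref, alt, true_genotype = genotype)]
  dc <- as.data.table(ds_calls)
  if (nrow(dc)) {
    dc <- dc[, .(chrom, pos, ref, alt, called_genotype = genotype)]
    cls <- merge(tr, dc, by = c("chrom", "pos", "ref", "alt"), all.x = TRUE)
  } else {
    cls <- copy(tr)[, called_genotype := NA_character_]
  }
  cls[, outcome := fifelse(is.na(called_genotype), "FN",
                    fifelse(called_genotype == true_genotype, "TP",
                      fifelse(true_genotype == "het",
                              "PTP_het_called_hom", "PTP_hom_called_het")))]
  cls[, depth_at_site := depth_at(ds_depth, chrom, pos)]
  if (anyNA(cls$depth_at_site))
    stop_contract("truth position outside the down-sampled depth profile's target")
  cls[, `:=`(downsample_p = p, replicate_id = replicate_id,
             called_genotype = NULL)]
  setorder(cls, chrom, pos)
  cls[]
}

#' Genotype-specific sensitivity as a function of read depth
#'
#' Sensitivity at depth d is `TP / (TP + PTP + FN)` over classified truth
#' records of the requested genotype class. Two binnings are available:
#' `"cumulative_le_d"` pools all observations with depth <= d into row d;
#' `"exact_d"` bins observations at exactly depth d (the form needed for a
#' per-depth comparison with the binomial expectation and for per-base
#' scoring). Depths above `max_depth` are clamped into the top row. Rows
#' with an empty denominator have `sensitivity = NA` (undefined, not zero).
#'
#' @param cls classifications pooled over down-sampling probabilities and
#'   replicates.
#' @param genotype `"het"` or `"hom"`.
#' @param mode `"exact_d"` (default) or `"cumulative_le_d"`.
#' @param max_depth top depth row (default 100).
#' @return `data.table`: `depth` (0..max_depth), `genotype`, `n_tp`,
#'   `n_ptp`, `n_fn`, `sensitivity`; attribute `mode`.
#' @export
sensitivity_curve <- function(cls, genotype = c("het", "hom"),
                              mode = c("exact_d", "cumulative_le_d"),
                              max_depth = 100L) {
  genotype <- match.arg(genotype)
  mode <- match.arg(mode)
  cc <- as.data.table(cls)[true_genotype == genotype]
  cc[, depth := pmin(depth_at_site, max_depth)]
  grid <- data.table(depth = 0:max_depth)
  tab <- cc[, .(n_tp = sum(outcome == "TP"),
                n_ptp = sum(startsWith(outcome, "PTP")),
                n_fn = sum(outcome == "FN")), by = depth]
  tab <- merge(grid, tab, by = "depth", all.x = TRUE)
  for (col in c("n_tp", "n_ptp", "n_fn"))
    set(tab, which(is.na(tab[[col]])), col, 0L)
  if (mode == "cumulative_le_d")
    tab[, `:=`(n_tp = cumsum(n_tp), n_ptp = cumsum(n_ptp), n_fn = cumsum(n_fn))]
  tab[, genotype := genotype]
  denom <- tab$n_tp + tab$n_ptp + tab$n_fn
  tab[, sensitivity := fifelse(denom > 0, n_tp / pmax(denom, 1L), NA_real_)]
  setcolorder(tab, c("depth", "genotype", "n_tp", "n_ptp", "n_fn", "sensitivity"))
  setattr(tab, "mode", mode)
  tab[]
}

#' Naive binomial sensitivity expectation
#'
#' The idealized expectation against which the empirical curve is compared:
#' at depth d a heterozygous site yields `k ~ Binomial(d, 1/2)` alt reads
#' (all d reads alt for a homozygous site), all at uniform quality `q` with
#' no sequencing error, and the caller's own decision rule is applied by
#' exact enumeration over k. The returned value is the probability that a
#' variant is emitted *and* the genotype is correct.
#'
#' @param d read depth (>= 0).
#' @param genotype `"het"` or `"hom"`.
#' @param params a `caller_params` object.
#' @param q uniform Phred quality of the idealized observations.
#' @return probability in `[0, 1]`; vectorized over `d`.
#' @export
binomial_expectation <- function(d, genotype = c("het", "hom"),
                                 params = caller_params(), q = 30) {
  genotype <- match.arg(genotype)
  vapply(as.integer(d), function(dd) {
    if (dd <= 0L) return(0)
    if (genotype == "hom") {
      dec <- decide_genotype(0L, dd, q, params)
      return(as.numeric(dec$genotype == "hom"))
    }
    k <- 0:dd
    dec <- decide_genotype(dd - k, k, q, params)
    sum(dbinom(k, dd, 0.5) * (dec$genotype == "het"))
  }, numeric(1))
}

#' Genotype concordance between two call sets
#'
#' Over sites called in both sets with matching alleles, the fraction with
#' identical genotype, reported separately for heterozygous and homozygous
#' calls as classified by set A. Sites present in only one set are counted
#' but not part of the concordance denominator.
#'
#' @param calls_a,calls_b variant-call tables on shared coordinates.
#' @return list with `het`, `hom` (fractions, `NA` when the class is empty
#'   in the intersection), `n_het`, `n_hom`, `n_only_a`, `n_only_b`.
#' @export
genotype_concordance <- function(calls_a, calls_b) {
  a <- as.data.table(calls_a)[, .(chrom, pos, ref, alt, gt_a = genotype)]
  b <- as.data.table(calls_b)[, .(chrom, pos, ref, alt, gt_b = genotype)]
  m <- merge(a, b, by = c("chrom", "pos", "ref", "alt"))
  conc <- function(g) {
    sub <- m[gt_a == g]
    if (nrow(sub) == 0L) return(NA_real_)
    mean(sub$gt_b == g)
  }
  list(het = conc("het"), hom = conc("hom"),
       n_het = nrow(m[gt_a == "het"]), n_hom = nrow(m[gt_a == "hom"]),
       n_only_a = nrow(a) - nrow(m), n_only_b = nrow(b) - nrow(m))
}

#' Run the down-sampling calibration pipeline
#'
#' Builds the truth set from the full alignment, then for each inclusion
#' probability: down-samples the reads pair-preservingly, calls genotypes at
#' the truth positions, computes the down-sampled depth profile and
#' classifies every truth record. Classifications are pooled across all
#' probabilities before curve estimation, mirroring pooling across
#' down-sampled alignments.
#'
#' @param reads full-alignment reads.
#' @param panel known polymorphic sites (`chrom`, `pos`, `ref`, `alt`).
#' @param target a `target_set`.
#' @param reference named character vector of sequences.
#' @param probabilities down-sampling probabilities (default 0.1..0.9 by 0.1).
#' @param params a `caller_params` object.
#' @param seed seed for the down-sampler.
#' @param max_depth top row of the resulting curves.
#' @param qual_filter optional Phred filter for truth-set construction.
#' @return list: `truth`, `classifications`, `curves` (exact-depth, both
#'   genotypes, rbind-ed), `curves_cumulative`, `full_calls`, `full_profile`.
#' @export
run_calibration <- function(reads, panel, target, reference,
                            probabilities = seq(0.1, 0.9, by = 0.1),
                            params = caller_params(), seed = 1L,
                            max_depth = 100L, qual_filter = NULL) {
  if (any(probabilities <= 0 | probabilities >= 1) ||
      anyDuplicated(probabilities) || is.unsorted(probabilities))
    stop_input("probabilities must be unique, sorted, strictly in (0, 1)")
  pan <- as.data.table(panel)
  full_profile <- compute_depth_profile(reads, target)
  pan_pos <- unique(pan[, .(chrom, pos)])
  full_calls <- call_variants(reads, target, reference, params,
                              positions = pan_pos, profile = full_profile)
  truth <- build_truth_set(full_calls, pan, target, qual_filter)
  cls <- vector("list", length(probabilities))
  for (i in seq_along(probabilities)) {
    p <- probabilities[i]
    ds <- downsample_reads(reads, p, seed)
    prof <- compute_depth_profile(ds, target)
    calls <- call_variants(ds, target, reference, params,
                           positions = truth[, .(chrom, pos)], profile = prof)
    cls[[i]] <- classify_downsampled(truth, calls, prof, p)
  }
  cls <- rbindlist(cls)
  curves <- rbind(sensitivity_curve(cls, "het", "exact_d", max_depth),
                  sensitivity_curve(cls, "hom", "exact_d", max_depth))
  curves_cum <- rbind(sensitivity_curve(cls, "het", "cumulative_le_d", max_depth),
                      sensitivity_curve(cls, "hom", "cumulative_le_d", max_depth))
  list(truth = truth, classifications = cls, curves = curves,
       curves_cumulative = curves_cum, full_calls = full_calls,
       full_profile = full_profile)
}

#' Fill undefined rows of a calibration table
#'
#' Down-sampling runs on small experiments leave depth bins with no
#' observations (`sensitivity = NA`). For scoring, such gaps can be closed by
#' linear interpolation between the nearest defined depths; leading gaps fall
#' back to 0 (no observation shallower than the first defined bin) and
#' trailing gaps carry the last defined value forward. Counts are left
#' untouched, so filled rows remain recognizable by their `NA` counts.
#'
#' @param curves long-form calibration table.
#' @return the table with `sensitivity` gap-filled per genotype.
#' @export
fill_recall_table <- function(curves) {
  dt <- as.data.table(curves)
  dt[, sensitivity := {
    s <- sensitivity
    if (all(is.na(s))) stop_input("calibration table has no defined rows")
    ok <- which(!is.na(s))
    filled <- approx(depth[ok], s[ok], xout = depth, rule = 2)$y
    if (ok[1] > 1L) filled[seq_len(ok[1] - 1L)] <- 0
    filled[depth == 0L] <- 0
    filled
  }, by = genotype]
  dt[]
}

#' Read/write calibration (recall) tables
#'
#' The native dialect is a tab-delimited file with a header and columns
#' `depth`, `genotype`, `n_tp`, `n_ptp`, `n_fn`, `sensitivity` — one row per
#' (depth, genotype); round trips are exact. `read_recall_table()` also
#' accepts a minimal 3-column dialect `depth`, `het_sensitivity`,
#' `hom_sensitivity`, which is converted to the long form with `NA` counts.
#'
#' @param curves a curve table (both genotypes rbind-ed).
#' @param path file path.
#' @return `read_recall_table()` a long-form curve `data.table`;
#'   `write_recall_table()` the path, invisibly.
#' @export
write_recall_table <- function(curves, path) {
  dt <- as.data.table(curves)[, .(depth, genotype, n_tp, n_ptp, n_fn, sensitivity)]
  fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_recall_table
#' @export
read_recall_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  long_cols <- c("depth", "genotype", "n_tp", "n_ptp", "n_fn", "sensitivity")
  if (all(long_cols %in% names(dt))) {
    out <- dt[, long_cols, with = FALSE]
  } else if (all(c("depth", "het_sensitivity", "hom_sensitivity") %in% names(dt))) {
    out <- rbind(
      dt[, .(depth, genotype = "het", n_tp = NA_integer_, n_ptp = NA_integer_,
             n_fn = NA_integer_, sensitivity = het_sensitivity)],
      dt[, .(depth, genotype = "hom", n_tp = NA_integer_, n_ptp = NA_integer_,
             n_fn = NA_integer_, sensitivity = hom_sensitivity)])
  } else {
    stop_input("unrecognized recall table dialect: %s", path)
  }
  setorder(out, genotype, depth)
  out[]
}
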