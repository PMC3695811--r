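#' Parameters for a synthetic exome-capture experiment
#'
#' The generator emulates the features of targeted capture that drive
#' depth-dependent SNV detection sensitivity: merged target intervals,
#' per-tile capture-efficiency heterogeneity (lognormal, plus a G+C-linked
#' component), uniform per-base sequencing error at the matching Phred
#' quality, diploid genotypes at planted polymorphic sites, optional bias
#' toward capturing reference-allele fragments, and paired reads emitted at
#' their true coordinates (no aligner in the loop).
#'
#' @param seed integer seed; every downstream quantity is deterministic
#'   given it.
#' @param n_targets number of target intervals.
#' @param target_len_range min/max target interval length (bp).
#' @param mean_depth expected on-target read depth when biases are off.
#' @param read_len read length (bp).
#' @param paired emit read pairs (two reads per fragment).
#' @param fragment_len_mean,fragment_len_sd fragment length distribution
#'   (bp); fragments are clamped to at least `2 * read_len` so mates never
#'   overlap.
#' @param error_rate per-base substitution probability; base qualities are
#'   uniform at `round(-10*log10(error_rate))` (60 when 0).
#' @param het_site_rate,hom_site_rate per-base probability of planting a
#'   heterozygous / homozygous-alt SNV.
#' @param capture_cv coefficient of variation of per-tile capture
#'   efficiency (lognormal with mean 1).
#' @param gc_bias_slope multiplicative efficiency change per unit G+C
#'   fraction deviation from 0.5 (negative: GC-rich tiles captured worse).
#' @param ref_bias reference-allele capture bias in (0, 1]: an alt-carrying
#'   fragment survives capture with probability `ref_bias` per heterozygous
#'   alt allele it carries, with rejected fragments replaced by fresh draws,
#'   so the accepted haplotype at a fragment covering m het sites has odds
#'   alt:ref of `ref_bias^m : 1` and total depth is unchanged. At an isolated
#'   het site the expected alt read fraction is `ref_bias / (1 + ref_bias)`
#'   (1/3 at 0.5); 1 means unbiased 1:1 sampling.
#' @param gc_mean,gc_sd G+C composition of the simulated reference, varying
#'   in 100-bp windows.
#' @param intergap_range min/max gap between target intervals; keep the
#'   minimum at or above the fragment length so intervals receive
#'   independent coverage.
#' @param sample_id sample label carried on reads.
#' @return a validated list of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L, n_targets = 50L,
                              target_len_range = c(120L, 400L),
                              mean_depth = 30, read_len = 76L, paired = TRUE,
                              fragment_len_mean = 250, fragment_len_sd = 25,
                              error_rate = 1e-3,
                              het_site_rate = 1e-3, hom_site_rate = 1e-3,
                              capture_cv = 0.3, gc_bias_slope = -1,
                              ref_bias = 1, gc_mean = 0.45, gc_sd = 0.1,
                              intergap_range = c(300L, 800L),
                              sample_id = "sim01") {
  p <- list(seed = as.integer(seed), n_targets = as.integer(n_targets),
            target_len_range = as.integer(target_len_range),
            mean_depth = mean_depth, read_len = as.integer(read_len),
            paired = isTRUE(paired), fragment_len_mean = fragment_len_mean,
            fragment_len_sd = fragment_len_sd, error_rate = error_rate,
            het_site_rate = het_site_rate, hom_site_rate = hom_site_rate,
            capture_cv = capture_cv, gc_bias_slope = gc_bias_slope,
            ref_bias = ref_bias, gc_mean = gc_mean, gc_sd = gc_sd,
            intergap_range = as.integer(intergap_range),
            sample_id = sample_id)
  rates <- c(p$error_rate, p$het_site_rate, p$hom_site_rate)
  if (any(rates < 0 | rates > 1)) stop_input("rates must be in [0, 1]")
  if (p$mean_depth <= 0) stop_input("mean_depth must be > 0")
  if (p$capture_cv < 0) stop_input("capture_cv must be >= 0")
  if (p$ref_bias <= 0 || p$ref_bias > 1) stop_input("ref_bias must be in (0, 1]")
  if (p$n_targets < 1L || p$read_len < 1L) stop_input("n_targets/read_len must be >= 1")
  if (diff(p$target_len_range) < 0 || p$target_len_range[1] < 1L)
    stop_input("bad target_len_range")
  structure(p, class = "simulation_params")
}

# independent deterministic RNG stream per stage, derived from (seed, label)
derive_seed <- function(seed, label) {
  as.integer(floor(.pair_hash01(label, as.numeric(seed)) * .Machine$integer.max))
}

genome_length <- function(params) {
  per <- max(params$target_len_range) + max(params$intergap_range)
  as.integer(params$n_targets * per + max(params$intergap_range) + 2000L)
}

#' Simulate a reference sequence with varying local G+C
#'
#' G+C content is drawn per 100-bp window from a truncated normal so that
#' G+C-linked capture bias is exercisable downstream.
#'
#' @param params a `simulation_params` object.
#' @return named character vector of chromosome sequences (single `chr1`).
#' @export
simulate_reference <- function(params) {
  set.seed(derive_seed(params$seed, "reference"))
  L <- genome_length(params)
  nwin <- (L + 99L) %/% 100L
  gc_w <- pmin(pmax(rnorm(nwin, params$gc_mean, params$gc_sd), 0.2), 0.8)
  p_gc <- rep(gc_w, each = 100L)[seq_len(L)]
  is_gc <- runif(L) < p_gc
  half <- runif(L) < 0.5
  bases <- ifelse(is_gc, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
  c(chr1 = paste0(bases, collapse = ""))
}

#' Simulate target intervals on a reference
#'
#' Intervals with uniform lengths in `target_len_range`, separated by gaps
#' in `intergap_range`, merged into a `target_set`.
#'
#' @param reference named character vector from [simulate_reference()].
#' @param params a `simulation_params` object.
#' @return a `target_set`.
#' @export
simulate_targets <- function(reference, params) {
  set.seed(derive_seed(params$seed, "targets"))
  lens <- sample(params$target_len_range[1]:params$target_len_range[2],
                 params$n_targets, replace = TRUE)
  gaps <- sample(params$intergap_range[1]:params$intergap_range[2],
                 params$n_targets, replace = TRUE)
  starts <- cumsum(c(gaps[1] + 500L, lens[-length(lens)] + gaps[-1]))
  ends <- starts + lens
  if (max(ends) + 500L > nchar(reference[[1]]))
    stop_contract("simulated targets exceed the reference length")
  merge_intervals(genomic_intervals(names(reference)[1], starts, ends),
                  label = params$sample_id)
}

#' Plant diploid truth genotypes at random targeted sites
#'
#' Each targeted base independently becomes a heterozygous SNV with
#' probability `het_site_rate` or a homozygous-alt SNV with
#' `hom_site_rate`; the alt allele is uniform over the three non-reference
#' bases.
#'
#' @param reference named character vector of sequences.
#' @param target a `target_set`.
#' @param params a `simulation_params` object.
#' @return `data.table` with `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `genotype` (`"het"`/`"hom"`).
#' @export
simulate_truth <- function(reference, target, params) {
  set.seed(derive_seed(params$seed, "truth"))
  iv <- target$intervals
  lens <- iv$end - iv$start
  pos <- unlist(lapply(seq_len(nrow(iv)),
                       function(i) seq.int(iv$start[i], iv$end[i] - 1L)))
  chrom <- rep(iv$chrom, lens)
  u <- runif(length(pos))
  h <- params$het_site_rate; a <- params$hom_site_rate
  cat_het <- u < h
  cat_hom <- !cat_het & u < h + a
  keep <- cat_het | cat_hom
  if (!any(keep))
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character()))
  dt <- data.table(chrom = chrom[keep], pos = pos[keep],
                   genotype = ifelse(cat_het[keep], "het", "hom"))
  dt[, ref := toupper(substring(reference[chrom], pos + 1L, pos + 1L))]
  acgt <- c("A", "C", "G", "T")
  shift <- sample.int(3L, nrow(dt), replace = TRUE)
  dt[, alt := acgt[((match(ref, acgt) - 1L + shift) %% 4L) + 1L]]
  dt <- dt[ref %in% acgt]
  setorder(dt, chrom, pos)
  dt[]
}

#' Write a truth set as a single-sample VCF
#'
#' @param truth a truth `data.table` from [simulate_truth()].
#' @param sample sample name.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_vcf <- function(truth, sample, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=senscall-simulate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  ), con)
  if (nrow(truth)) {
    gt <- ifelse(truth$genotype == "hom", "1/1", "0/1")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                       truth$chrom, truth$pos + 1L, truth$ref, truth$alt, gt), con)
  }
  invisible(path)
}

#' Simulate capture-sequencing reads over a target set
#'
#' Per 100-bp tile, a capture efficiency multiplier
#' `e = lognormal(mean 1, cv = capture_cv) * (1 + gc_bias_slope * (gc - 0.5))`
#' (truncated at 0) scales the expected depth. Fragment starts are placed by a
#' Poisson process whose intensity is chosen so that every targeted position
#' has expected depth `mean_depth * e` of its local tiles. Each fragment
#' copies one haplotype (heterozygous sites: haplotype 1:1, then retained with
#' probability `ref_bias` per alt allele carried, otherwise re-drawn from the
#' reference haplotype); per-base sequencing errors substitute uniformly among
#' the other three bases. Reads are emitted pre-aligned at their true
#' positions with all-M CIGARs.
#'
#' @param reference named character vector of sequences.
#' @param target a `target_set`.
#' @param truth truth table from [simulate_truth()].
#' @param params a `simulation_params` object.
#' @return an aligned-read `data.table`, coordinate sorted.
#' @export
simulate_reads <- function(reference, target, truth, params) {
  set.seed(derive_seed(params$seed, "reads"))
  R <- params$read_len
  paired <- params$paired
  flen_nom <- if (paired) as.integer(round(params$fragment_len_mean)) else R
  if (paired && flen_nom < 2L * R)
    stop_input("fragment_len_mean must be >= 2 * read_len for paired reads")
  bases_per_frag <- if (paired) 2L * R else R

  tiles <- tile_targets(target, 100L)
  tiles[, gc := tile_gc(tiles, reference)]
  sigma <- sqrt(log(1 + params$capture_cv^2))
  tiles[, eff := rlnorm(.N, meanlog = -sigma^2 / 2, sdlog = sigma) *
          (1 + params$gc_bias_slope * (gc - 0.5))]
  tiles[, eff := pmax(eff, 0)]

  iv <- target$intervals
  chrom_len <- setNames(nchar(reference), names(reference))

  # per-interval start windows [start - flen + 1, end - 1] with per-position
  # intensity mean_depth * eff(tile) / bases_per_frag; flank positions take
  # the first tile's efficiency
  frag_list <- vector("list", nrow(iv))
  for (i in seq_len(nrow(iv))) {
    tl <- tiles[parent_id == i]
    w0 <- max(0L, iv$start[i] - flen_nom + 1L)
    w1 <- min(iv$end[i] - 1L, chrom_len[[iv$chrom[i]]] - flen_nom)
    if (w1 < w0) next
    wpos <- w0:w1
    tix <- findInterval(wpos, tl$start)  # 0 for flank -> first tile
    mu <- params$mean_depth * tl$eff[pmax(tix, 1L)] / bases_per_frag
    n <- rpois(1L, sum(mu))
    if (n == 0L) next
    starts <- sample(wpos, n, replace = TRUE, prob = mu)
    frag_list[[i]] <- data.table(chrom = iv$chrom[i], fstart = starts)
  }
  frags <- rbindlist(frag_list)
  if (nrow(frags) == 0L)
    return(aligned_reads(character(), character(), integer(), character(),
                         character(), character()))
  nfrag <- nrow(frags)
  frags[, frag_id := .I]
  if (paired) {
    flen <- as.integer(round(rnorm(nfrag, params$fragment_len_mean,
                                   params$fragment_len_sd)))
    flen <- pmax(flen, 2L * R)
    # fragment must fit its chromosome
    flen <- pmin(flen, chrom_len[frags$chrom] - frags$fstart)
    flen <- pmax(flen, 2L * R)
    frags[, flen := flen]
  } else {
    frags[, flen := R]
  }

  # reads: one (unpaired) or two (mates at fragment ends) per fragment
  reads <- if (paired) {
    rbind(frags[, .(frag_id, chrom, pos = fstart, mate = 1L)],
          frags[, .(frag_id, chrom, pos = fstart + flen - R, mate = 2L)])
  } else {
    frags[, .(frag_id, chrom, pos = fstart, mate = 0L)]
  }
  setorder(reads, frag_id, mate)
  reads[, read_id := .I]
  reads[, bases := substring(reference[chrom], pos + 1L, pos + R)]

  # haplotypes and planted alleles ------------------------------------------
  hap <- rbinom(nfrag, 1L, 0.5)  # 1 = alt-carrying haplotype at het sites
  site_hits <- NULL
  if (nrow(truth)) {
    # foverlaps treats intervals as closed: use inclusive ends
    tr <- copy(truth)[, `:=`(start = pos, end = pos, site_id = .I)]
    rv <- reads[, .(read_id, chrom, start = pos, end = pos + R - 1L)]
    setkey(tr, chrom, start, end)
    site_hits <- foverlaps(setkey(rv, chrom, start, end), tr, nomatch = NULL)
    site_hits <- site_hits[, .(read_id, site_id, spos = start,
                               alt = alt, genotype = genotype)]
    site_hits[, frag_id := reads$frag_id[read_id]]
    if (params$ref_bias < 1) {
      # rejection sampling with replacement draws, collapsed to its
      # renormalized form: an alt-haplotype fragment carrying m het alt
      # alleles survives capture with probability ref_bias^m, so the
      # accepted haplotype is alt with odds ref_bias^m : 1
      m <- site_hits[genotype == "het", .(m = uniqueN(site_id)), by = frag_id]
      qb <- params$ref_bias^m$m / (1 + params$ref_bias^m$m)
      hap[m$frag_id] <- rbinom(nrow(m), 1L, qb)
    }
    # hom-alt sites are on both haplotypes; het alt only on haplotype 1
    apply_alt <- site_hits[genotype == "hom" |
                             (genotype == "het" & hap[frag_id] == 1L)]
    if (nrow(apply_alt)) {
      bs <- reads$bases
      off <- apply_alt$spos - reads$pos[apply_alt$read_id] + 1L
      for (k in seq_len(nrow(apply_alt))) {
        i <- apply_alt$read_id[k]
        substr(bs[i], off[k], off[k]) <- apply_alt$alt[k]
      }
      reads[, bases := bs]
    }
  }

  # sequencing errors --------------------------------------------------------
  if (params$error_rate > 0) {
    totb <- nrow(reads) * R
    nerr <- rbinom(1L, totb, params$error_rate)
    if (nerr > 0L) {
      lin <- sample.int(totb, nerr)
      ri <- ((lin - 1L) %/% R) + 1L
      oi <- ((lin - 1L) %% R) + 1L
      acgt <- c("A", "C", "G", "T")
      cur <- substring(reads$bases[ri], oi, oi)
      new <- acgt[((match(cur, acgt) - 1L + sample.int(3L, nerr, TRUE)) %% 4L) + 1L]
      bs <- reads$bases
      for (k in seq_len(nerr)) {
        substr(bs[ri[k]], oi[k], oi[k]) <- new[k]
      }
      reads[, bases := bs]
    }
  }

  # error-free reads still claim a finite quality: Q40, the usual Illumina cap
  q <- if (params$error_rate > 0) {
    as.integer(round(-10 * log10(params$error_rate)))
  } else 40L
  qstr <- strrep(rawToChar(as.raw(q + 33L)), R)
  flag <- if (paired) ifelse(reads$mate == 1L, 99L, 147L) else 0L
  # flags 99/147: paired, proper pair, mate-strand bits; pre-aligned sim reads
  out <- aligned_reads(
    name = sprintf("%s_frag%07d", params$sample_id, reads$frag_id),
    chrom = reads$chrom, pos = reads$pos,
    cigar = sprintf("%dM", R), bases = reads$bases,
    quals = qstr, flag = flag, mapq = 60L, sample_id = params$sample_id)
  setorder(out, chrom, pos)
  out[]
}

#' Run a full synthetic experiment
#'
#' Convenience wrapper: reference, targets, truth, reads, and the full
#' alignment's depth profile, all deterministic given `params$seed`.
#'
#' @param params a `simulation_params` object.
#' @return list with `reference`, `target`, `truth`, `reads`, `profile`,
#'   `params`.
#' @export
simulate_experiment <- function(params) {
  reference <- simulate_reference(params)
  target <- simulate_targets(reference, params)
  truth <- simulate_truth(reference, target, params)
  reads <- simulate_reads(reference, target, truth, params)
  profile <- compute_depth_profile(reads, target)
  list(reference = reference, target = target, truth = truth,
       reads = reads, profile = profile, params = params)
}
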