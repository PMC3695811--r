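#' Diploid caller parameters
#'
#' A GATK-style diploid genotype-likelihood model with theta-style priors.
#' The default emit threshold of Phred 30 corresponds to an expected 0.1%
#' false call rate, the commonly used quality cutoff.
#'
#' @param theta_het prior probability of a heterozygous genotype.
#' @param theta_hom prior probability of a homozygous-alt genotype.
#' @param call_threshold Phred-scaled quality required to emit a variant:
#'   `-10*log10 P(hom-ref | data)` must reach it.
#' @return a validated list of class `caller_params`.
#' @export
caller_params <- function(theta_het = 1e-3, theta_hom = 5e-4,
                          call_threshold = 30) {
  if (theta_het < 0 || theta_hom < 0 || theta_het + theta_hom >= 1)
    stop_input("genotype priors must be >= 0 and sum to < 1")
  if (call_threshold < 0) stop_input("call_threshold must be >= 0")
  structure(list(theta_het = theta_het, theta_hom = theta_hom,
                 call_threshold = call_threshold), class = "caller_params")
}

#' Down-sample reads, preserving read pairs
#'
#' Each read pair (or unpaired read) is kept independently with probability
#' `p`. The decision is one uniform draw per read *name*, derived by hashing
#' `(seed, name)`: mates are never separated, the result is deterministic
#' given the seed and independent of read order, and the kept-set at a lower
#' `p` is nested inside the kept-set at any higher `p` under the same seed
#' (so sensitivity curves are monotone in `p` on a fixed sample).
#'
#' @param reads aligned-read table.
#' @param p inclusion probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the kept subset of `reads`.
#' @export
downsample_reads <- function(reads, p, seed = 1L) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop_input("inclusion probability p must be a number in [0, 1]")
  if (nrow(reads) == 0L || p == 1) return(as.data.table(reads))
  u <- .pair_hash01(reads$name, as.numeric(seed))
  as.data.table(reads)[u < p]
}

#' Pileup observations at selected positions
#'
#' Collects `(base, quality)` observations from reads whose M operations
#' cover each position. Deletions contribute to depth but supply no base and
#' so do not appear here.
#'
#' @param reads aligned-read table.
#' @param positions `data.table` with `chrom` and `pos` (0-based).
#' @return `data.table` with `chrom`, `pos`, `base`, `obs_qual` (integer
#'   Phred), one row per observation.
#' @export
pileup_at <- function(reads, positions) {
  pts <- as.data.table(positions)[, .(chrom = as.character(chrom),
                                      pos = as.integer(pos))]
  empty <- data.table(chrom = character(), pos = integer(),
                      base = character(), obs_qual = integer())
  if (nrow(pts) == 0L || nrow(reads) == 0L) return(empty)
  r <- as.data.table(reads)
  r[, read_id := .I]
  simple <- grepl("^\\d+M$", r$cigar)
  out <- list()

  # foverlaps treats intervals as closed; points are [pos, pos], reads
  # [pos, pos + len - 1]
  pts_iv <- copy(pts)[, `:=`(start = pos, end = pos)]
  setkey(pts_iv, chrom, start, end)

  if (any(simple)) {
    rs <- r[simple, .(read_id, chrom, start = pos,
                      end = pos + nchar(bases) - 1L, rpos = pos)]
    setkey(rs, chrom, start, end)
    ov <- foverlaps(pts_iv, rs, nomatch = NULL)
    if (nrow(ov)) {
      qoff <- ov$i.start - ov$rpos + 1L
      out[[1]] <- data.table(
        chrom = ov$chrom, pos = ov$i.start,
        base = substring(r$bases[ov$read_id], qoff, qoff),
        obs_qual = as.integer(charToRaw(paste0(
          substring(r$quals[ov$read_id], qoff, qoff), collapse = ""))) - 33L)
    }
  }
  if (any(!simple)) {
    cx <- list()
    for (i in which(!simple)) {
      mo <- cigar_m_offsets(r$cigar[i], r$pos[i])
      if (length(mo$refpos) == 0L) next
      cx[[length(cx) + 1L]] <- data.table(chrom = r$chrom[i],
                                          pos = mo$refpos, qoff = mo$qoff,
                                          read_id = i)
    }
    if (length(cx)) {
      cxt <- rbindlist(cx)
      cxt <- merge(cxt, pts, by = c("chrom", "pos"))
      if (nrow(cxt)) {
        out[[length(out) + 1L]] <- cxt[, .(
          chrom, pos,
          base = substring(r$bases[read_id], qoff, qoff),
          obs_qual = as.integer(charToRaw(paste0(
            substring(r$quals[read_id], qoff, qoff), collapse = ""))) - 33L)]
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- rbindlist(out)
  setorder(res, chrom, pos)
  res[]
}

#' Diploid genotype log-likelihoods for one pileup column
#'
#' With per-observation error probability `eps = 10^(-q/10)`:
#' `P(b | hom G) = 1 - eps` if `b == G`, else `eps / 3`;
#' `P(b | het) = 0.5 * P(b | hom ref) + 0.5 * P(b | hom alt)`.
#' The column log-likelihood is the sum over observations, computed in log
#' space. An empty column yields flat (all zero) log-likelihoods.
#'
#' @param col list with `ref` (reference base) and `obs`, a data.frame with
#'   `base` and `qual`.
#' @param alt the alternate allele, distinct from `col$ref`.
#' @return named numeric vector of natural-log likelihoods
#'   `c(hom_ref, het, hom_alt)`.
#' @export
genotype_likelihoods <- function(col, alt) {
  if (identical(alt, col$ref)) stop_input("alt must differ from ref")
  obs <- col$obs
  if (is.null(obs) || nrow(obs) == 0L)
    return(c(hom_ref = 0, het = 0, hom_alt = 0))
  eps <- phred_to_prob(obs$qual)
  p_ref <- ifelse(obs$base == col$ref, 1 - eps, eps / 3)
  p_alt <- ifelse(obs$base == alt, 1 - eps, eps / 3)
  c(hom_ref = sum(log(p_ref)),
    het = sum(log(0.5 * p_ref + 0.5 * p_alt)),
    hom_alt = sum(log(p_alt)))
}

# genotype posteriors from log-likelihood matrix (cols hom_ref, het, hom_alt)
genotype_posteriors <- function(ll, params) {
  lp <- sweep(ll, 2L, log(c(1 - params$theta_het - params$theta_hom,
                            params$theta_het, params$theta_hom)), `+`)
  lse <- logsumexp_rows(lp)
  exp(lp - lse)
}

# the caller's decision for a column of n_ref ref and n_alt alt observations
# at uniform Phred q; closed form used by binomial_expectation and tests
decide_genotype <- function(n_ref, n_alt, q, params = caller_params()) {
  eps <- phred_to_prob(q)
  ll <- cbind(hom_ref = n_ref * log(1 - eps) + n_alt * log(eps / 3),
              het = (n_ref + n_alt) * log(0.5 * (1 - eps) + 0.5 * eps / 3),
              hom_alt = n_alt * log(1 - eps) + n_ref * log(eps / 3))
  post <- genotype_posteriors(ll, params)
  qual <- -10 / log(10) * (log(post[, "hom_ref"]))
  qual <- pmin(ifelse(is.nan(qual), Inf, qual), 9999)
  gt <- ifelse(post[, "het"] >= post[, "hom_alt"], "het", "hom")
  # no alt-supporting observation -> no candidate allele -> never emitted,
  # matching call_variants()
  list(genotype = ifelse(n_alt > 0L & qual >= params$call_threshold, gt, "none"),
       qual = qual)
}

#' Call diploid SNV genotypes from pileups
#'
#' Per targeted position: the candidate alt allele is the non-reference base
#' with the highest summed quality; genotype posteriors combine the diploid
#' likelihoods with priors `(1 - theta_het - theta_hom, theta_het,
#' theta_hom)`; a variant is emitted iff the Phred-scaled probability that
#' the genotype is not hom-ref reaches `call_threshold`. The reported
#' `depth` uses the depth-profile definition (M+D), even though genotyping
#' uses M-covering observations only.
#'
#' @param reads aligned-read table.
#' @param target a `target_set`.
#' @param reference named character vector of sequences.
#' @param params a `caller_params` object.
#' @param positions optional `data.table(chrom, pos)` restricting calling to
#'   those positions (e.g. a known-site panel); default: every targeted
#'   position.
#' @param profile optional precomputed `depth_profile` of `reads`.
#' @return variant-call `data.table`: `chrom`, `pos`, `ref`, `alt`,
#'   `genotype` (`"het"`/`"hom"`), `qual`, `depth`.
#' @export
call_variants <- function(reads, target, reference, params = caller_params(),
                          positions = NULL, profile = NULL) {
  if (is.null(profile)) profile <- compute_depth_profile(reads, target)
  if (is.null(positions)) positions <- profile_positions(profile)[, .(chrom, pos)]
  positions <- as.data.table(positions)[, .(chrom = as.character(chrom),
                                            pos = as.integer(pos))]
  empty <- data.table(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character(),
                      qual = numeric(), depth = integer())
  obs <- pileup_at(reads, positions)
  if (nrow(obs) == 0L) return(empty)
  obs[, ref := toupper(substring(reference[chrom], pos + 1L, pos + 1L))]
  obs <- obs[base %in% c("A", "C", "G", "T") & ref %in% c("A", "C", "G", "T")]
  if (nrow(obs) == 0L) return(empty)

  # candidate alt: non-ref base with max summed quality; ties by base order
  altq <- obs[base != ref, .(sq = sum(obs_qual)), by = .(chrom, pos, base)]
  if (nrow(altq) == 0L) return(empty)
  setorder(altq, chrom, pos, -sq, base)
  alts <- altq[, .SD[1L], by = .(chrom, pos)][, .(chrom, pos, alt = base)]
  obs <- merge(obs, alts, by = c("chrom", "pos"))

  eps <- phred_to_prob(obs$obs_qual)
  p_ref <- ifelse(obs$base == obs$ref, 1 - eps, eps / 3)
  p_alt <- ifelse(obs$base == obs$alt, 1 - eps, eps / 3)
  obs[, `:=`(l_ref = log(p_ref), l_het = log(0.5 * p_ref + 0.5 * p_alt),
             l_alt = log(p_alt))]
  site <- obs[, .(ref = ref[1L], alt = alt[1L], ll_ref = sum(l_ref),
                  ll_het = sum(l_het), ll_hom = sum(l_alt)),
              by = .(chrom, pos)]
  post <- genotype_posteriors(
    as.matrix(site[, .(hom_ref = ll_ref, het = ll_het, hom_alt = ll_hom)]),
    params)
  qual <- -10 / log(10) * log(post[, "hom_ref"])
  qual <- pmin(ifelse(is.nan(qual) | is.infinite(qual), 9999, qual), 9999)
  site[, qual := qual]
  site[, genotype := ifelse(post[, "het"] >= post[, "hom_alt"], "het", "hom")]
  calls <- site[qual >= params$call_threshold,
                .(chrom, pos, ref, alt, genotype, qual)]
  if (nrow(calls) == 0L) return(empty)
  calls[, depth := depth_at(profile, chrom, pos)]
  setorder(calls, chrom, pos)
  calls[]
}
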