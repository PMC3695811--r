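library(data.table)

# quick read constructor: all-M cigar, uniform quality
mk_reads <- function(pos, chrom = "chr1", len = 10L, name = NULL, q = 30L,
                     bases = NULL, flag = 0L, cigar = NULL) {
  n <- length(pos)
  if (is.null(name)) name <- sprintf("r%04d", seq_len(n))
  if (is.null(cigar)) cigar <- sprintf("%dM", len)
  qlen <- senscall::cigar_query_len(cigar)
  if (is.null(bases)) bases <- vapply(qlen, function(l) strrep("A", l), "")
  quals <- vapply(seq_len(n), function(i) strrep(rawToChar(as.raw(q + 33L)),
                                                 nchar(bases[i])), "")
  aligned_reads(name = name, chrom = chrom, pos = pos, cigar = cigar,
                bases = bases, quals = quals, flag = flag)
}

# brute-force positional-union length of raw intervals (boolean mask)
oracle_union_length <- function(iv, domain = 6000L) {
  tot <- 0L
  for (cn in unique(iv$chrom)) {
    mask <- logical(domain)
    sub <- iv[iv$chrom == cn, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      mask[(sub$start[i] + 1L):sub$end[i]] <- TRUE
    tot <- tot + sum(mask)
  }
  tot
}

# O(reads x positions) depth oracle; M and D ops cover, I and S do not
oracle_depth <- function(reads, target) {
  pp <- profile_positions(compute_depth_profile(reads[0], target))
  depth <- integer(nrow(pp))
  span <- senscall::cigar_ref_span(reads$cigar)
  for (i in seq_len(nrow(reads))) {
    hit <- pp$chrom == reads$chrom[i] & pp$pos >= reads$pos[i] &
      pp$pos < reads$pos[i] + span[i]
    depth[hit] <- depth[hit] + 1L
  }
  depth
}

# random reference for caller tests: all-A so alt alleles are visible
flat_reference <- function(len = 1000L, chrom = "chr1", base = "A") {
  setNames(strrep(base, len), chrom)
}

# a small deterministic simulated world shared by several test files
sim_world <- function(seed = 42L, ...) {
  simulate_experiment(simulation_params(seed = seed, ...))
}
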