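# classed conditions: input errors map to CLI exit code 2, contract
# violations to 3
stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("senscall_input_error", "error")))
}

stop_contract <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("senscall_contract_error", "error")))
}

#' Phred scale conversions
#'
#' `phred_to_prob()` converts a Phred-scaled quality Q to the error
#' probability 10^(-Q/10); `prob_to_phred()` is the inverse.
#'
#' @param q Phred-scaled quality (numeric vector).
#' @param p error probability in (0, 1].
#' @return numeric vector.
#' @export
phred_to_prob <- function(q) 10^(-q / 10)

#' @rdname phred_to_prob
#' @export
prob_to_phred <- function(p) -10 * log10(p)

# numerically stable log(sum(exp(x))) over rows of a matrix
logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# SAM/FASTQ quality string (Phred+33) <-> integer vectors
quals_to_int <- function(qs) {
  lapply(qs, function(s) as.integer(charToRaw(s)) - 33L)
}

int_to_quals <- function(qi) {
  vapply(qi, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
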