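#' @importFrom rlang .data .env abort warn
#' @importFrom dplyr %>%
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Error-mixed success probability for a true allele copy fraction
#'
#' A read drawn from a genome carrying the alternate allele at copy fraction
#' `g` reports the alternate base with probability `g` when read correctly and
#' with probability `1 - g` when miscalled, giving
#' `p = g (1 - e) + (1 - g) e`.
#'
#' @param g true alternate-allele copy fraction in `[0, 1]`.
#' @param e per-read error rate in `(0, 0.5)`.
#' @return numeric vector of success probabilities.
#' @keywords internal
error_mix <- function(g, e) g * (1 - e) + (1 - g) * e

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    abort(sprintf("`%s` must lie in [%g, %g]", name, lo, hi))
  }
  invisible(x)
}

#' Valid alternate-allele copy fractions for a ploidy
#'
#' Diploids carry 0, 1 or 2 copies of the alternate allele (copy fractions
#' 0, 1/2, 1); triploids carry 0..3 copies (0, 1/3, 2/3, 1).
#'
#' @param ploidy integer, 2 or 3.
#' @return numeric vector of copy fractions `(0:ploidy) / ploidy`.
#' @export
copy_fractions <- function(ploidy) {
  stopifnot(ploidy %in% c(1L, 2L, 3L))
  (0:ploidy) / ploidy
}

# Derive a per-stage RNG seed from a master seed so stages can be rerun in
# isolation. Kept below .Machine$integer.max.
derive_seed <- function(master_seed, stage) {
  stage_index <- match(
    stage,
    c("simulate", "ploidy", "genotype", "lineages", "infer", "clones", "metagenome")
  )
  if (is.na(stage_index)) stage_index <- 97L
  as.integer((as.numeric(master_seed) * 1000003 + stage_index * 7919) %% 2147483629)
}
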