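#' Allele-frequency spectrum of a clonal isolate
#'
#' Collects the heterozygous (intermediate-frequency) sites of one clone:
#' sites with depth at least `min_depth` and `0 < x < d`. Homozygous sites are
#' excluded because the spectrum peaks at 0 and 1 are shared by every ploidy
#' and carry no information for the diploid-versus-triploid comparison; only
#' the positions of the intermediate peaks (1/2 versus 1/3 and 2/3) do.
#'
#' @param vm long variant tibble ([read_variant_table()]).
#' @param clone sample identifier of the clone.
#' @param min_depth minimum depth for a site to be informative (default 10).
#' @return a tibble with columns `clone`, `site`, `alt_count`, `depth`.
#' @export
build_spectrum <- function(vm, clone, min_depth = 10) {
  if (!clone %in% vm$sample) abort(sprintf("clone '%s' not present in variant table", clone))
  sub <- dplyr::filter(
    vm, .data$sample == .env$clone,
    .data$depth >= .env$min_depth,
    .data$alt_count > 0, .data$alt_count < .data$depth
  )
  tibble::tibble(
    clone = clone, site = sub$site,
    alt_count = sub$alt_count, depth = sub$depth
  )
}

# Per-site log-likelihood of a spectrum under one ploidy model: an
# equal-weight binomial mixture over all copy fractions of the ploidy
# (0, 1/2, 1 for diploid; 0, 1/3, 2/3, 1 for triploid), error-mixed at rate
# e. The 0 and 1 components are shared between the models but must be
# present: error reads leak homozygous sites into the 0 < x < d spectrum,
# and without a component near 0 or 1 such sites would be wildly
# misattributed to whichever model's nearest heterozygous peak is closer.
spectrum_loglik <- function(x, d, ploidy, error_rate) {
  fracs <- copy_fractions(ploidy)
  ll_site <- vapply(seq_along(x), function(i) {
    comp <- stats::dbinom(x[i], d[i], error_mix(fracs, error_rate), log = TRUE)
    logsumexp(comp) - log(length(fracs))
  }, numeric(1))
  sum(ll_site)
}

#' Classify a clone as diploid or triploid from its allele-frequency spectrum
#'
#' Formalizes the visual rule that a diploid's allele-frequency spectrum
#' peaks at 0, 1/2 and 1 while a triploid's peaks at 0, 1/3, 2/3 and 1: each
#' informative site contributes a binomial likelihood under each ploidy's
#' equal-weight mixture over its copy fractions, adjusted for the per-read
#' error rate. The 0 and 1 components are retained in both models because
#' error reads leak homozygous sites into the intermediate-frequency
#' spectrum. The summed log-likelihoods are compared and the
#' higher-likelihood ploidy returned, with `delta_loglik` = diploid minus
#' triploid (positive means diploid).
#'
#' @param spectrum tibble from [build_spectrum()].
#' @param error_rate per-read error rate (default 0.005).
#' @param min_sites minimum number of informative sites required for a call
#'   (default 50); below this the call is `NA` with reason
#'   `"insufficient data"`.
#' @param conf_threshold calls with `|delta_loglik|` below this are flagged
#'   as low confidence (default 10).
#' @return one-row tibble: `clone`, `ploidy` (2, 3 or `NA`), `delta_loglik`,
#'   `n_sites`, `confident`, `reason`.
#' @export
classify_ploidy <- function(spectrum, error_rate = 0.005, min_sites = 50,
                            conf_threshold = 10) {
  check_prob(error_rate, "error_rate", lo = 1e-12, hi = 0.5)
  clone <- if (nrow(spectrum) > 0) spectrum$clone[1] else NA_character_
  if (nrow(spectrum) < min_sites) {
    return(tibble::tibble(
      clone = clone, ploidy = NA_integer_, delta_loglik = NA_real_,
      n_sites = nrow(spectrum), confident = FALSE,
      reason = "insufficient data"
    ))
  }
  ll2 <- spectrum_loglik(spectrum$alt_count, spectrum$depth, 2L, error_rate)
  ll3 <- spectrum_loglik(spectrum$alt_count, spectrum$depth, 3L, error_rate)
  delta <- ll2 - ll3
  tibble::tibble(
    clone = clone,
    ploidy = if (delta >= 0) 2L else 3L,
    delta_loglik = delta,
    n_sites = nrow(spectrum),
    confident = abs(delta) >= conf_threshold,
    reason = NA_character_
  )
}

#' Call ploidy for a set of clones
#'
#' Applies [build_spectrum()] and [classify_ploidy()] to each clone. Clones
#' that cannot be called (too few informative sites) get an `NA` ploidy with
#' a reason rather than an error, so one problematic isolate never aborts a
#' batch.
#'
#' @inheritParams build_spectrum
#' @inheritParams classify_ploidy
#' @param clones character vector of clone sample ids; defaults to every
#'   sample in `vm`.
#' @return tibble with one row per clone, in input order; columns as in
#'   [classify_ploidy()].
#' @export
call_ploidies <- function(vm, clones = NULL, min_depth = 10, error_rate = 0.005,
                          min_sites = 50, conf_threshold = 10) {
  if (is.null(clones)) clones <- unique(vm$sample)
  if (length(clones) == 0) {
    return(tibble::tibble(
      clone = character(), ploidy = integer(), delta_loglik = double(),
      n_sites = integer(), confident = logical(), reason = character()
    ))
  }
  missing_clones <- setdiff(clones, unique(vm$sample))
  if (length(missing_clones) > 0) {
    abort(sprintf("clone(s) not in variant table: %s", paste(missing_clones, collapse = ", ")))
  }
  purrr::map_dfr(clones, function(cl) {
    res <- classify_ploidy(
      build_spectrum(vm, cl, min_depth = min_depth),
      error_rate = error_rate, min_sites = min_sites,
      conf_threshold = conf_threshold
    )
    res$clone <- cl
    res
  })
}
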