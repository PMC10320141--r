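#' Posterior over allele copy-number states at one site of one clone
#'
#' For a clone of known ploidy, the alternate-allele count at a site is
#' modeled as `x ~ Binomial(d, p_c)` where the success probability for copy
#' number `c` is the error-mixed copy fraction
#' `p_c = (c/ploidy) (1 - e) + (1 - c/ploidy) e`. Under a uniform prior over
#' the `ploidy + 1` copy-number states, the posterior is the normalized
#' vector of binomial likelihoods.
#'
#' @param x alternate-allele read count.
#' @param d total depth; must satisfy `0 <= x <= d`.
#' @param ploidy 2 or 3.
#' @param error_rate per-read error rate `e` in `(0, 0.5)`.
#' @return a tibble with one row per copy-number state: `copies`, `g`
#'   (`copies/ploidy`), `loglik`, `posterior` (sums to 1).
#' @export
genotype_posterior <- function(x, d, ploidy, error_rate = 0.005) {
  stopifnot(length(x) == 1, length(d) == 1)
  if (x < 0 || x > d) abort("alt count must satisfy 0 <= x <= depth")
  check_prob(error_rate, "error_rate", lo = 1e-12, hi = 0.5 - 1e-12)
  g <- copy_fractions(ploidy)
  ll <- stats::dbinom(x, d, error_mix(g, error_rate), log = TRUE)
  post <- exp(ll - logsumexp(ll))
  tibble::tibble(
    copies = 0:ploidy, g = g, loglik = ll, posterior = post / sum(post)
  )
}

# Vectorized MAP genotype call for one ploidy: returns copies, g, posterior.
genotype_map_vec <- function(x, d, ploidy, error_rate) {
  g <- copy_fractions(ploidy)
  p <- error_mix(g, error_rate)
  ll <- vapply(p, function(pc) stats::dbinom(x, d, pc, log = TRUE), numeric(length(x)))
  ll <- matrix(ll, nrow = length(x))
  m <- apply(ll, 1, max)
  w <- exp(ll - m)
  post <- w / rowSums(w)
  map_idx <- max.col(post, ties.method = "first")
  list(
    copies = map_idx - 1L,
    g = g[map_idx],
    posterior = post[cbind(seq_along(x), map_idx)]
  )
}

#' Call per-site genotypes for all clones
#'
#' Applies the copy-number posterior ([genotype_posterior()]) to every clone
#' and site and keeps the maximum a posteriori state. Calls are set to
#' missing (`g = NA`) when depth is below `min_depth` or the posterior of the
#' MAP state is below `posterior_threshold`; missing calls are tolerated by
#' the downstream marker-selection rules rather than imputed. Clones with an
#' unknown ploidy are excluded with a warning and listed in the
#' `"excluded_clones"` attribute.
#'
#' @param vm long variant tibble restricted to (or containing) the clones.
#' @param ploidy_calls tibble from [call_ploidies()] (columns `clone`,
#'   `ploidy`).
#' @param min_depth minimum depth for a call (default 8).
#' @param posterior_threshold minimum MAP posterior for a call (default 0.95).
#' @param error_rate per-read error rate (default 0.005).
#' @return a `clone_genotypes` tibble with one row per clone x site:
#'   `clone`, `site`, `ploidy`, `copies`, `g`, `posterior` (`g`, `copies`,
#'   `posterior` are `NA` where the call is missing). Every clone/site
#'   combination is present, including zero-depth sites. Attribute `ploidy`
#'   carries the per-clone ploidies used.
#' @export
call_genotypes <- function(vm, ploidy_calls, min_depth = 8,
                           posterior_threshold = 0.95, error_rate = 0.005) {
  known <- dplyr::filter(ploidy_calls, !is.na(.data$ploidy))
  unknown <- setdiff(ploidy_calls$clone, known$clone)
  if (length(unknown) > 0) {
    warn(sprintf(
      "excluding clone(s) with unknown ploidy: %s", paste(unknown, collapse = ", ")
    ))
  }
  if (nrow(known) == 0) abort("no clones with a known ploidy")
  all_sites <- unique(vm$site)
  sub <- dplyr::filter(vm, .data$sample %in% known$clone)
  sub <- dplyr::inner_join(
    sub, dplyr::select(known, clone = "clone", "ploidy"),
    by = c(sample = "clone")
  )

  called <- purrr::map_dfr(c(2L, 3L), function(p) {
    block <- dplyr::filter(sub, .data$ploidy == p)
    if (nrow(block) == 0) return(NULL)
    res <- genotype_map_vec(block$alt_count, block$depth, p, error_rate)
    tibble::tibble(
      clone = block$sample, site = block$site, ploidy = p,
      copies = res$copies, g = res$g, posterior = res$posterior,
      depth = block$depth
    )
  })
  gate <- called$depth < min_depth | called$posterior < posterior_threshold
  called$copies[gate] <- NA_integer_
  called$g[gate] <- NA_real_
  called$posterior[gate] <- NA_real_
  called$depth <- NULL

  # complete to the full clone x site grid (absent rows are missing calls)
  grid <- tidyr::expand_grid(clone = known$clone, site = all_sites)
  out <- dplyr::left_join(grid, called, by = c("clone", "site"))
  out$ploidy <- known$ploidy[match(out$clone, known$clone)]
  out <- tibble::new_tibble(out, class = "clone_genotypes")
  attr(out, "ploidy") <- known[, c("clone", "ploidy")]
  attr(out, "excluded_clones") <- unknown
  attr(out, "site_order") <- all_sites
  out
}

#' Genotype matrix view of clone genotype calls
#'
#' @param genotypes a `clone_genotypes` tibble from [call_genotypes()].
#' @return a clones x sites numeric matrix of copy fractions `g`
#'   (`NA` = missing call), with dimnames.
#' @export
genotype_matrix <- function(genotypes) {
  clones <- unique(genotypes$clone)
  sites <- attr(genotypes, "site_order")
  if (is.null(sites)) sites <- unique(genotypes$site)
  m <- matrix(NA_real_, length(clones), length(sites),
    dimnames = list(clones, sites)
  )
  m[cbind(match(genotypes$clone, clones), match(genotypes$site, sites))] <- genotypes$g
  m
}

#' Write a clones x sites genotype matrix as TSV
#'
#' States are encoded as copy numbers, `.` for missing.
#'
#' @inheritParams genotype_matrix
#' @param path output TSV path.
#' @export
write_genotype_table <- function(genotypes, path) {
  wide <- tidyr::pivot_wider(
    dplyr::mutate(genotypes,
      code = ifelse(is.na(.data$copies), ".", as.character(.data$copies))
    )[, c("clone", "site", "code")],
    names_from = "site", values_from = "code"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
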