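#' Generations elapsed from periodic fractional growth
#'
#' A population that grows by a fraction `r` each cycle and is then culled
#' back to its working size completes `log2(1 + r)` doublings — generations —
#' per cycle. An 8-month season at 30 days/month with two 12-hour cycles a
#' day gives 480 cycles; at 10% growth per cycle that is about 66
#' generations.
#'
#' @param n_cycles number of growth cycles (e.g. `8 * 30 * 2` for an 8-month
#'   season of 12-hour cycles).
#' @param r fractional growth per cycle (e.g. 0.10 for 10%).
#' @return number of generations, `n_cycles * log2(1 + r)`.
#' @export
generations_from_growth <- function(n_cycles, r) {
  stopifnot(n_cycles >= 0)
  if (any(r <= -1)) abort("growth fraction must exceed -1")
  n_cycles * log2(1 + r)
}

#' Expected total number of de novo mutations over a season
#'
#' `mu * genome_bp * ploidy * N * generations`: each of `N` individuals
#' carries `ploidy` copies of a `genome_bp`-sized genome, each base mutating
#' at rate `mu` per generation.
#'
#' @param mu per-bp per-generation mutation rate (e.g. `5e-10`).
#' @param genome_bp haploid genome size in bp (default `1.2e7`, budding-yeast
#'   scale).
#' @param ploidy genome copies per cell.
#' @param n population size.
#' @param generations generations elapsed.
#' @return expected mutation count.
#' @export
mutation_supply <- function(mu, genome_bp = 1.2e7, ploidy = 2, n, generations) {
  stopifnot(mu >= 0, genome_bp >= 0, ploidy >= 0, n >= 0, generations >= 0)
  mu * genome_bp * ploidy * n * generations
}

#' Expected recurrence of one specific substitution per generation
#'
#' How many times per generation one particular single-base substitution
#' (one site, one specific alternate base of the three possible) arises in
#' the population: `(mu / 3) * ploidy * N`.
#'
#' @inheritParams mutation_supply
#' @return expected occurrences per generation.
#' @export
per_site_substitution_supply <- function(mu, ploidy = 2, n) {
  stopifnot(mu >= 0, ploidy >= 0, n >= 0)
  (mu / 3) * ploidy * n
}

#' Clonal diversity summary of a genotype matrix
#'
#' Counts, per segregating site, the number of clones carrying the alternate
#' allele (`g > 0` among non-missing calls) and summarizes the site-frequency
#' distribution: singletons (present in exactly one clone), sites present in
#' every clone, and the full histogram. Percentage denominators are the
#' segregating sites of the matrix (sites present in at least one clone).
#'
#' @param genotypes `clone_genotypes` tibble or genotype matrix.
#' @return list: `n_sites` (segregating), `n_clones`, `n_singletons`,
#'   `pct_singletons`, `n_in_all`, `pct_in_all`, `histogram` (tibble
#'   `n_clones_present`, `n_sites`).
#' @export
diversity_summary <- function(genotypes) {
  G <- if (is.matrix(genotypes)) genotypes else genotype_matrix(genotypes)
  if (nrow(G) == 0 || ncol(G) == 0) abort("empty genotype matrix")
  present <- colSums(G > 0, na.rm = TRUE)
  nonmissing <- colSums(!is.na(G))
  seg <- present >= 1
  n_sites <- sum(seg)
  if (n_sites == 0) abort("no segregating sites in the genotype matrix")
  counts <- present[seg]
  n_singletons <- sum(counts == 1)
  # "in all clones" requires presence in every clone with a non-missing call
  n_in_all <- sum(counts == nonmissing[seg] & counts == nrow(G))
  hist_tb <- tibble::as_tibble(table(n_clones_present = counts))
  hist_tb$n_clones_present <- as.integer(hist_tb$n_clones_present)
  names(hist_tb)[2] <- "n_sites"
  hist_tb$n_sites <- as.integer(hist_tb$n_sites)
  list(
    n_sites = n_sites, n_clones = nrow(G),
    n_singletons = n_singletons, pct_singletons = 100 * n_singletons / n_sites,
    n_in_all = n_in_all, pct_in_all = 100 * n_in_all / n_sites,
    histogram = hist_tb
  )
}

#' Overlap between two variant catalogues
#'
#' @param a,b character vectors of variant keys (e.g. `"chrom:pos:alt"`), or
#'   tibbles with columns `chrom`, `pos`, `alt`.
#' @return tibble: `n_a`, `n_b`, `n_intersection`, `pct_of_a`
#'   (`100 |A∩B| / |A|`), `pct_of_b` (`100 |A∩B| / |B|`).
#' @export
catalogue_overlap <- function(a, b) {
  as_keys <- function(x) {
    if (is.data.frame(x)) unique(paste(x$chrom, x$pos, x$alt, sep = ":")) else unique(as.character(x))
  }
  ka <- as_keys(a)
  kb <- as_keys(b)
  n_int <- length(intersect(ka, kb))
  tibble::tibble(
    n_a = length(ka), n_b = length(kb), n_intersection = n_int,
    pct_of_a = if (length(ka) > 0) 100 * n_int / length(ka) else NA_real_,
    pct_of_b = if (length(kb) > 0) 100 * n_int / length(kb) else NA_real_
  )
}
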