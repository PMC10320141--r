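#' Configuration for a synthetic fermentation season
#'
#' Defaults describe the study conditions the package is validated under: a
#' mixed-ploidy population of 8 nested lineages (3 founders — one starter plus
#' invaders — and 5 lineages nested within them), 20 synapomorphic markers per
#' lineage, 15 metagenomic timepoints, metagenome depth ~90x and clone depth
#' ~25x, and a small per-read error rate. Trajectories follow discrete-time
#' logistic competition: exclusive lineage masses are multiplied by
#' `exp(s_l)` each step and renormalized, with invaders and new sublineages
#' entering at their origin step at a small initial frequency. A background
#' "untracked diversity" component (the residual) competes neutrally.
#'
#' @param n_lineages total number of lineages (default 8).
#' @param n_founders number of top-level lineages (default 3); the first is
#'   the starter (present at step 0), later founders are invaders.
#' @param p_triploid probability a founder subtree is triploid (default 0.4).
#' @param markers_per_lineage synapomorphic markers planted per lineage
#'   (default 20).
#' @param n_background non-marker sites (default 4840, for ~5,000 sites in
#'   total): a mix of homoplasic sites shared by several founders and a pool
#'   of zero-frequency sites used for clone-private mutations.
#' @param n_timepoints metagenomic timepoints (default 15).
#' @param days_between days between timepoints (default 14).
#' @param fitness_sd standard deviation of per-step selection coefficients
#'   `s_l` (default 0.15); set 0 for neutral dynamics.
#' @param fitness optional numeric vector of per-lineage selection
#'   coefficients, recycled to `n_lineages`; overrides the random draw.
#' @param invader_freq initial frequency of an entering lineage (default 0.03).
#' @param residual_init initial untracked-background frequency (default 0.05).
#' @param metagenome_depth mean per-site metagenome depth (default 90).
#' @param clone_depth mean per-site clone depth (default 25).
#' @param error_rate per-read error rate (default 0.002).
#' @param clones_per_lineage clones picked per lineage under the coverage
#'   sampling plan (default 4).
#' @param private_sites_per_clone clone-private mutations added per sampled
#'   clone from the zero-frequency pool (default 3).
#' @param wright_fisher_n effective population size for optional multinomial
#'   drift jitter between steps; `Inf` (default) disables drift so
#'   trajectories are deterministic given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_lineages = 8, n_founders = 3, p_triploid = 0.4,
                       markers_per_lineage = 20, n_background = 4840,
                       n_timepoints = 15, days_between = 14,
                       fitness_sd = 0.15, fitness = NULL, invader_freq = 0.03,
                       residual_init = 0.05,
                       metagenome_depth = 90, clone_depth = 25,
                       error_rate = 0.002, clones_per_lineage = 4,
                       private_sites_per_clone = 3,
                       wright_fisher_n = Inf) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_lineages >= 1, cfg$n_founders >= 1, cfg$n_founders <= cfg$n_lineages,
    cfg$markers_per_lineage >= 1, cfg$n_timepoints >= 1,
    cfg$metagenome_depth >= 1, cfg$clone_depth >= 1
  )
  check_prob(cfg$p_triploid, "p_triploid")
  check_prob(cfg$error_rate, "error_rate", lo = 0, hi = 0.5)
  if (cfg$invader_freq * (cfg$n_founders - 1) + cfg$residual_init >= 1) {
    abort("invader initial frequencies plus residual exceed 1; infeasible config")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the ground truth of a synthetic season
#'
#' Builds the lineage tree (founders at the top level, later lineages
#' attached to a uniformly chosen existing lineage in the same founder
#' subtree), assigns one ploidy per founder subtree, plants each lineage's
#' markers at copy fractions valid for that ploidy, and generates
#' inclusive-frequency trajectories by logistic competition among exclusive
#' masses. The truth satisfies the nested-sum constraints at every timepoint
#' and the planted markers satisfy the synapomorphy definition exactly.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; the same seed reproduces the truth
#'   exactly.
#' @return a `sim_truth` list: `lineages` (tibble `lineage`, `parent`,
#'   `ploidy`, `fitness`, `origin_step`), `markers` (tibble `site`, `lineage`,
#'   `g_m`), `background` (tibble `site`, `carriers`, `class`),
#'   `trajectories` (tibble `timepoint`, `lineage`, `frequency`, `exclusive`,
#'   `residual`), `timepoints`, `sites` (tibble of all site records), and the
#'   config.
#' @export
simulate_truth <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(seed, "simulate"))
  n <- config$n_lineages
  ids <- sprintf("L%02d", seq_len(n))
  parent <- rep(NA_character_, n)
  founder_of <- character(n)
  founders <- ids[seq_len(config$n_founders)]
  founder_of[seq_len(config$n_founders)] <- founders
  for (i in seq_len(n)[-seq_len(config$n_founders)]) {
    p <- sample(seq_len(i - 1), 1)
    parent[i] <- ids[p]
    founder_of[i] <- founder_of[p]
  }
  ploidy_founder <- stats::setNames(
    ifelse(stats::runif(config$n_founders) < config$p_triploid, 3L, 2L), founders
  )
  ploidy <- ploidy_founder[founder_of]
  fitness <- if (!is.null(config$fitness)) {
    rep_len(config$fitness, n)
  } else {
    stats::rnorm(n, 0, config$fitness_sd)
  }

  # origin steps: starter founder at 0; invaders and sublineages enter in the
  # first two thirds of the season (always after their parent)
  origin <- integer(n)
  horizon <- max(1L, floor(config$n_timepoints * 2 / 3))
  for (i in seq_len(n)) {
    if (ids[i] == founders[1]) {
      origin[i] <- 0L
    } else {
      lo <- if (is.na(parent[i])) 1L else origin[match(parent[i], ids)] + 1L
      origin[i] <- if (lo >= horizon) lo else sample(lo:horizon, 1)
    }
  }

  lineages <- tibble::tibble(
    lineage = ids, parent = parent, founder = founder_of,
    ploidy = as.integer(ploidy), fitness = fitness, origin_step = origin
  )

  # markers: constant copy fraction per site across all clade members
  marker_fracs <- function(p) if (p == 2L) c(1 / 2, 1) else c(1 / 3, 2 / 3, 1)
  markers <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      lineage = ids[i],
      g_m = sample(marker_fracs(ploidy[i]), config$markers_per_lineage, replace = TRUE)
    )
  })
  n_marker <- nrow(markers)

  # background (non-marker) sites, three classes:
  #  - ancestral_het: heterozygous in every founder (ancestral polymorphism;
  #    per-founder copy fraction drawn from that founder's het states) — these
  #    give clones their genome-wide intermediate allele-frequency spectrum
  #  - homoplasic: homozygous in >=2 but not all founders (violates the clean
  #    clade pattern, so never a marker)
  #  - zero: absent from the population; pool for clone-private mutations
  het_fracs <- function(p) if (p == 2L) 1 / 2 else c(1 / 3, 2 / 3)
  n_het <- round(config$n_background * 0.5)
  n_homo <- if (config$n_founders >= 3) round(config$n_background * 0.15) else 0L
  n_zero <- config$n_background - n_het - n_homo
  het_rows <- tibble::tibble(
    class = rep("ancestral_het", n_het),
    carriers = rep(list(founders), n_het),
    g_carrier = purrr::map(seq_len(n_het), function(i) {
      vapply(founders, function(fo) {
        sample(rep(het_fracs(ploidy_founder[[fo]]), 2), 1)
      }, numeric(1))
    })
  )
  homo_rows <- tibble::tibble(
    class = rep("homoplasic", n_homo),
    carriers = purrr::map(seq_len(n_homo), function(i) {
      k <- sample(2:(config$n_founders - 1), 1)
      sort(sample(founders, k))
    })
  )
  if (n_homo > 0) {
    homo_rows$g_carrier <- purrr::map(homo_rows$carriers, function(cs) {
      stats::setNames(rep(1, length(cs)), cs)
    })
  } else {
    homo_rows$g_carrier <- list()
  }
  background <- dplyr::bind_rows(
    het_rows, homo_rows,
    tibble::tibble(
      class = rep("zero", n_zero),
      carriers = rep(list(character(0)), n_zero),
      g_carrier = rep(list(numeric(0)), n_zero)
    )
  )

  # lay sites down a toy genome
  n_sites <- n_marker + nrow(background)
  pos <- sort(sample.int(12e6, n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  site_ids <- site_key("chrI", pos)
  ord_marker <- sample.int(n_sites, n_marker)
  sites <- tibble::tibble(
    chrom = "chrI", pos = pos, ref = ref, alt = unname(alt), site = site_ids
  )
  markers$site <- site_ids[sort(ord_marker)]
  background$site <- site_ids[setdiff(seq_len(n_sites), sort(ord_marker))]

  # trajectories: logistic competition on exclusive masses + residual
  steps <- seq_len(config$n_timepoints) - 1L
  excl <- matrix(0, nrow = config$n_timepoints, ncol = n, dimnames = list(NULL, ids))
  res <- numeric(config$n_timepoints)
  mass <- stats::setNames(rep(0, n), ids)
  mass[founders[1]] <- 1 - config$residual_init
  r_mass <- config$residual_init
  for (k in seq_along(steps)) {
    entering <- ids[origin == steps[k] & mass == 0 & ids != founders[1]]
    for (id in entering) {
      take <- min(config$invader_freq, 0.5 * sum(mass) + 0.5 * r_mass)
      scale <- 1 - take / (sum(mass) + r_mass)
      mass <- mass * scale
      r_mass <- r_mass * scale
      mass[id] <- take
    }
    excl[k, ] <- mass
    res[k] <- r_mass
    grown <- mass * exp(fitness)
    r_grown <- r_mass
    if (is.finite(config$wright_fisher_n)) {
      draw <- stats::rmultinom(1, config$wright_fisher_n,
        c(grown, r_grown) / sum(c(grown, r_grown))
      )[, 1]
      grown <- draw[seq_len(n)]
      r_grown <- draw[n + 1]
    }
    tot <- sum(grown) + r_grown
    mass <- grown / tot
    r_mass <- r_grown / tot
  }

  # inclusive frequency = own exclusive mass + all descendants'
  incl <- excl
  ord_ids <- lineage_order(lineages)
  for (id in rev(ord_ids$ids)) {
    kids <- ids[!is.na(parent) & parent == id]
    if (length(kids) > 0) incl[, id] <- incl[, id] + rowSums(incl[, kids, drop = FALSE])
  }
  timepoints <- steps * config$days_between
  trajectories <- tibble::tibble(
    timepoint = rep(timepoints, times = n),
    lineage = rep(ids, each = config$n_timepoints),
    frequency = as.vector(incl),
    exclusive = as.vector(excl),
    residual = rep(res, times = n)
  )

  structure(
    list(
      lineages = lineages, markers = markers, background = background,
      sites = sites, trajectories = trajectories, timepoints = timepoints,
      config = config, seed = seed
    ),
    class = "sim_truth"
  )
}

# lineage path from a lineage up to its founder (inclusive)
lineage_path <- function(truth, lineage) {
  ids <- truth$lineages$lineage
  parent <- truth$lineages$parent
  path <- character(0)
  p <- lineage
  while (!is.na(p)) {
    path <- c(path, p)
    p <- parent[match(p, ids)]
  }
  path
}

# true population alternate-allele frequency of every site at one timepoint
site_population_freq <- function(truth, timepoint) {
  traj <- dplyr::filter(truth$trajectories, .data$timepoint == .env$timepoint)
  f <- stats::setNames(traj$frequency, traj$lineage)
  freq <- stats::setNames(rep(0, nrow(truth$sites)), truth$sites$site)
  freq[truth$markers$site] <- truth$markers$g_m * f[truth$markers$lineage]
  bg <- truth$background[truth$background$class != "zero", ]
  if (nrow(bg) > 0) {
    freq[bg$site] <- vapply(seq_len(nrow(bg)), function(i) {
      cs <- bg$carriers[[i]]
      min(1, sum(bg$g_carrier[[i]] * f[cs]))
    }, numeric(1))
  }
  freq
}

#' Sample a metagenomic timepoint from simulated truth
#'
#' Per site, the expected alternate-allele frequency is the sum over lineages
#' carrying it of `g_m * F_l` (exactly `g_m * F_l` for markers, which are
#' private to one lineage), mixed with the per-read error rate; depth is
#' Poisson around the configured mean and the alternate count is binomial.
#'
#' @param truth a `sim_truth`.
#' @param timepoint one of `truth$timepoints`.
#' @param depth mean depth (default: config value).
#' @param error_rate per-read error rate (default: config value).
#' @param seed integer seed.
#' @param sample_name sample identifier for the output column.
#' @return a long variant tibble (one sample).
#' @export
sample_metagenome <- function(truth, timepoint, depth = NULL, error_rate = NULL,
                              seed = 1, sample_name = NULL) {
  if (!timepoint %in% truth$timepoints) {
    abort(sprintf("timepoint %s not in simulated range", format(timepoint)))
  }
  depth <- depth %||% truth$config$metagenome_depth
  error_rate <- error_rate %||% truth$config$error_rate
  sample_name <- sample_name %||% sprintf("meta_t%03d", as.integer(timepoint))
  set.seed(seed)
  freq <- site_population_freq(truth, timepoint)
  p <- error_mix(freq, error_rate)
  d <- stats::rpois(length(freq), depth)
  x <- stats::rbinom(length(freq), d, p)
  tibble::tibble(
    chrom = truth$sites$chrom, pos = truth$sites$pos,
    ref = truth$sites$ref, alt = truth$sites$alt, site = truth$sites$site,
    sample = sample_name, alt_count = as.integer(x), depth = as.integer(d)
  )
}

# genotype copy-fraction vector (over all sites) of a clone from `lineage`
clone_truth_genotype <- function(truth, lineage, private_sites = character(0),
                                 private_g = numeric(0)) {
  g <- stats::setNames(rep(0, nrow(truth$sites)), truth$sites$site)
  path <- lineage_path(truth, lineage)
  on_path <- truth$markers$lineage %in% path
  g[truth$markers$site[on_path]] <- truth$markers$g_m[on_path]
  founder <- truth$lineages$founder[match(lineage, truth$lineages$lineage)]
  bg <- truth$background[truth$background$class != "zero", ]
  if (nrow(bg) > 0) {
    gv <- vapply(seq_len(nrow(bg)), function(i) {
      idx <- match(founder, bg$carriers[[i]])
      if (is.na(idx)) 0 else bg$g_carrier[[i]][idx]
    }, numeric(1))
    g[bg$site] <- gv
  }
  if (length(private_sites) > 0) g[private_sites] <- private_g
  g
}

#' Sample clonal isolates from simulated truth
#'
#' Clones are drawn from lineages with probability proportional to their
#' exclusive frequencies at the timepoint (a draw landing in the untracked
#' residual is redrawn); each clone's per-site counts are binomial at its
#' error-mixed true copy fraction, with Poisson depth. Each clone also gets a
#' few private mutations from the zero-frequency background pool, emulating
#' clone-specific variants.
#'
#' @inheritParams sample_metagenome
#' @param n_clones number of clones to draw.
#' @param clone_depth mean depth (default: config value).
#' @param lineage_override optional character vector of length `n_clones`
#'   fixing each clone's lineage (used by the coverage sampling plan).
#' @param name_prefix prefix for clone sample ids.
#' @return list: `variants` (long variant tibble over all clones), `clone_map`
#'   (tibble `clone`, `lineage`, `timepoint`).
#' @export
sample_clones <- function(truth, timepoint, n_clones, clone_depth = NULL,
                          error_rate = NULL, seed = 1,
                          lineage_override = NULL, name_prefix = "clone") {
  if (!timepoint %in% truth$timepoints) {
    abort(sprintf("timepoint %s not in simulated range", format(timepoint)))
  }
  clone_depth <- clone_depth %||% truth$config$clone_depth
  error_rate <- error_rate %||% truth$config$error_rate
  set.seed(seed)
  traj <- dplyr::filter(truth$trajectories, .data$timepoint == .env$timepoint)
  w <- stats::setNames(traj$exclusive, traj$lineage)
  if (sum(w) <= 0) abort("all population mass is in the residual; nothing to sample")
  if (is.null(lineage_override)) {
    lin <- sample(names(w), n_clones, replace = TRUE, prob = w / sum(w))
  } else {
    stopifnot(length(lineage_override) == n_clones)
    lin <- lineage_override
  }
  zero_pool <- truth$background$site[truth$background$class == "zero"]
  n_priv <- truth$config$private_sites_per_clone
  priv_all <- if (n_priv > 0 && length(zero_pool) >= n_priv * n_clones) {
    sample(zero_pool, n_priv * n_clones)
  } else {
    character(0)
  }
  clones <- sprintf("%s_t%03d_%02d", name_prefix, as.integer(timepoint), seq_len(n_clones))
  variants <- purrr::map_dfr(seq_len(n_clones), function(i) {
    pl <- truth$lineages$ploidy[match(lin[i], truth$lineages$lineage)]
    priv <- if (length(priv_all) > 0) priv_all[((i - 1) * n_priv + 1):(i * n_priv)] else character(0)
    priv_g <- sample(copy_fractions(pl)[-1], length(priv), replace = TRUE)
    g <- clone_truth_genotype(truth, lin[i], priv, priv_g)
    d <- stats::rpois(length(g), clone_depth)
    x <- stats::rbinom(length(g), d, error_mix(g, error_rate))
    tibble::tibble(
      chrom = truth$sites$chrom, pos = truth$sites$pos,
      ref = truth$sites$ref, alt = truth$sites$alt, site = truth$sites$site,
      sample = clones[i], alt_count = as.integer(x), depth = as.integer(d)
    )
  })
  list(
    variants = variants,
    clone_map = tibble::tibble(clone = clones, lineage = lin, timepoint = timepoint)
  )
}

#' Simulate a complete season: truth, clones, metagenome series, sample sheet
#'
#' The coverage sampling plan picks `clones_per_lineage` clones per lineage,
#' each at a timepoint where the lineage is alive (so every lineage is
#' represented in the clone set, as the inference's parameter-recovery
#' validation requires); set `clone_plan = "proportional"` for realistic
#' frequency-proportional picking instead.
#'
#' @inheritParams simulate_truth
#' @param clone_plan `"coverage"` (default) or `"proportional"`.
#' @return list: `truth`, `clone_variants`, `clone_map`, `meta_variants`,
#'   `sample_sheet`, `clone_tree` (the true clone phylogeny as a `phylo`).
#' @export
simulate_season <- function(config = sim_config(), seed = 1,
                            clone_plan = c("coverage", "proportional")) {
  clone_plan <- match.arg(clone_plan)
  truth <- simulate_truth(config, seed)
  set.seed(derive_seed(seed, "clones"))

  ids <- truth$lineages$lineage
  excl <- tidyr::pivot_wider(
    truth$trajectories[, c("timepoint", "lineage", "exclusive")],
    names_from = "lineage", values_from = "exclusive"
  )
  if (clone_plan == "coverage") {
    plan <- purrr::map_dfr(ids, function(id) {
      alive <- excl$timepoint[excl[[id]] > 0.005]
      if (length(alive) == 0) alive <- excl$timepoint[which.max(excl[[id]])]
      tp <- rep(alive, length.out = max(config$clones_per_lineage, 1))
      tibble::tibble(lineage = id, timepoint = tp[sample.int(length(tp))])
    })
  } else {
    n_total <- config$clones_per_lineage * length(ids)
    tp <- sample(truth$timepoints, n_total, replace = TRUE)
    plan <- tibble::tibble(lineage = NA_character_, timepoint = tp)
  }

  clone_rows <- list()
  map_rows <- list()
  i <- 0
  for (t in sort(unique(plan$timepoint))) {
    i <- i + 1
    sel <- plan[plan$timepoint == t, ]
    drawn <- sample_clones(
      truth, t,
      n_clones = nrow(sel),
      seed = derive_seed(seed + i, "clones"),
      lineage_override = if (clone_plan == "coverage") sel$lineage else NULL
    )
    clone_rows[[length(clone_rows) + 1]] <- drawn$variants
    map_rows[[length(map_rows) + 1]] <- drawn$clone_map
  }
  clone_variants <- dplyr::bind_rows(clone_rows)
  clone_map <- dplyr::bind_rows(map_rows)

  meta_variants <- purrr::map_dfr(seq_along(truth$timepoints), function(k) {
    sample_metagenome(truth, truth$timepoints[k],
      seed = derive_seed(seed + k, "metagenome")
    )
  })

  sheet <- dplyr::bind_rows(
    tibble::tibble(
      sample = unique(meta_variants$sample), role = "metagenome",
      site_year = "sim", timepoint_days = truth$timepoints
    ),
    tibble::tibble(
      sample = clone_map$clone, role = "clone",
      site_year = "sim", timepoint_days = clone_map$timepoint
    )
  )

  list(
    truth = truth, clone_variants = clone_variants, clone_map = clone_map,
    meta_variants = meta_variants, sample_sheet = sheet,
    clone_tree = clone_tree_from_map(truth, clone_map)
  )
}

# True clone phylogeny: clones attach to their lineage's node in the
# lineage tree; clades of this tree are exactly the lineage memberships.
clone_tree_from_map <- function(truth, clone_map) {
  ids <- truth$lineages$lineage
  parent <- truth$lineages$parent
  build <- function(id) {
    kids_l <- ids[!is.na(parent) & parent == id]
    kids_c <- clone_map$clone[clone_map$lineage == id]
    parts <- c(kids_c, vapply(kids_l, build, ""))
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return("")
    if (length(parts) == 1) return(parts)
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  founders <- ids[is.na(parent)]
  parts <- vapply(founders, build, "")
  parts <- parts[nzchar(parts)]
  newick <- if (length(parts) == 1) {
    sprintf("%s;", parts)
  } else {
    sprintf("(%s);", paste(parts, collapse = ","))
  }
  validate_tree(ape::read.tree(text = newick))
}

#' Recovery error of inferred trajectories against simulated truth
#'
#' Matches each model lineage to the truth lineage with the largest marker
#' overlap and reports the root-mean-square error between inferred and true
#' inclusive frequencies over all matched lineage-timepoints.
#'
#' @param estimates `lineage_trajectories` tibble.
#' @param model the `lineage_model` used for the estimates.
#' @param truth the `sim_truth`.
#' @return list: `rmse` (scalar), `by_lineage` (tibble `lineage`,
#'   `truth_lineage`, `n_shared_markers`, `rmse`).
#' @export
trajectory_rmse <- function(estimates, model, truth) {
  match_tb <- purrr::map_dfr(unique(model$markers$lineage), function(l) {
    sites <- model$markers$site[model$markers$lineage == l]
    ov <- table(truth$markers$lineage[truth$markers$site %in% sites])
    if (length(ov) == 0) {
      return(tibble::tibble(lineage = l, truth_lineage = NA, n_shared_markers = 0L))
    }
    tibble::tibble(
      lineage = l, truth_lineage = names(ov)[which.max(ov)],
      n_shared_markers = as.integer(max(ov))
    )
  })
  joined <- dplyr::inner_join(
    dplyr::inner_join(
      estimates[, c("timepoint", "lineage", "frequency")],
      match_tb[!is.na(match_tb$truth_lineage), ], by = "lineage"
    ),
    dplyr::rename(
      truth$trajectories[, c("timepoint", "lineage", "frequency")],
      truth_lineage = "lineage", true_frequency = "frequency"
    ),
    by = c("timepoint", "truth_lineage")
  )
  if (nrow(joined) == 0) return(list(rmse = NA_real_, by_lineage = match_tb))
  err2 <- (joined$frequency - joined$true_frequency)^2
  by_lineage <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(joined, err2 = err2), .data$lineage, .data$truth_lineage
    ),
    n_shared_markers = dplyr::first(.data$n_shared_markers),
    rmse = sqrt(mean(.data$err2)), .groups = "drop"
  )
  list(rmse = sqrt(mean(err2)), by_lineage = by_lineage)
}

#' Clone-rarefaction validation of the full pipeline
#'
#' For each clone subsample size (and each seed), subsamples the season's
#' clone set, re-runs ploidy calling, genotyping, lineage-model construction
#' and trajectory inference on the subset, and reports the recovery RMSE
#' against truth over the lineages still identifiable. Median RMSE is
#' expected to be non-increasing in clone count. A subsample too small to
#' build any model is recorded as `NA`, not an exception.
#'
#' @param season output of [simulate_season()].
#' @param sizes integer vector of clone subsample sizes.
#' @param seeds integer vector of subsampling seeds (one replicate per seed).
#' @param min_markers,max_missing_frac lineage-model rules (defaults 10, 0.2).
#' @param eps,restarts inference settings.
#' @return tibble: `size`, `seed`, `n_lineages`, `rmse`.
#' @export
rarefaction_experiment <- function(season, sizes, seeds = 1:5,
                                   min_markers = 10, max_missing_frac = 0.2,
                                   eps = 0.002, restarts = 3) {
  all_clones <- season$clone_map$clone
  purrr::map_dfr(sizes, function(sz) {
    purrr::map_dfr(seeds, function(sd) {
      set.seed(derive_seed(sd, "clones") + sz)
      keep <- if (sz >= length(all_clones)) all_clones else sample(all_clones, sz)
      res <- tryCatch({
        cv <- dplyr::filter(season$clone_variants, .data$sample %in% keep)
        tree <- ape::keep.tip(season$clone_tree, keep)
        pl <- call_ploidies(cv)
        gt <- suppressWarnings(call_genotypes(cv, pl))
        tree <- ape::keep.tip(tree, intersect(tree$tip.label, unique(gt$clone)))
        model <- build_lineage_model(tree, gt,
          min_markers = min_markers, max_missing_frac = max_missing_frac
        )
        est <- infer_trajectories(model, season$meta_variants,
          season$sample_sheet,
          eps = eps, restarts = restarts, seed = sd
        )
        list(
          n_lineages = nrow(model$lineages),
          rmse = trajectory_rmse(est, model, season$truth)$rmse
        )
      }, error = function(e) list(n_lineages = NA_integer_, rmse = NA_real_))
      tibble::tibble(
        size = sz, seed = sd,
        n_lineages = res$n_lineages, rmse = res$rmse
      )
    })
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
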