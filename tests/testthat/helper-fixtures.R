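# Shared fixtures and independent oracles, all built in code at test time.

# A minimal lineage-model-like object for inference tests: `lineages` and
# `markers` are the only fields infer_frequencies() consumes.
make_toy_model <- function(lineages, markers) {
  structure(list(lineages = lineages, markers = markers), class = "lineage_model")
}

# Counts tibble for one metagenomic sample from (site, x, d) vectors.
make_counts <- function(site, alt_count, depth) {
  tibble::tibble(site = site, alt_count = alt_count, depth = depth)
}

# Independent binomial log-pmf (no dbinom): explicit log-factorial form.
log_binom_pmf <- function(x, d, p) {
  lgamma(d + 1) - lgamma(x + 1) - lgamma(d - x + 1) +
    x * log(p) + (d - x) * log1p(-p)
}

# Exhaustive grid-search oracle for <=3-lineage instances. The likelihood is
# separable, so each lineage's marker log-likelihood is tabulated on the grid
# and combinations are maximized under the nested constraints.
grid_search_loglik <- function(model, counts, eps, step = 0.005,
                               min_marker_depth = 10) {
  grid <- seq(0, 1, by = step)
  ids <- model$lineages$lineage
  parent <- model$lineages$parent
  joined <- dplyr::inner_join(model$markers, counts, by = "site")
  joined <- joined[joined$depth >= min_marker_depth, ]
  h <- lapply(ids, function(l) {
    m <- joined[joined$lineage == l, ]
    if (nrow(m) == 0) return(rep(0, length(grid)))
    vapply(grid, function(f) {
      p <- pmin(pmax(m$g_m * f, eps), 1 - eps)
      sum(log_binom_pmf(m$alt_count, m$depth, p))
    }, numeric(1))
  })
  names(h) <- ids
  n <- length(ids)
  top <- is.na(parent)
  if (n == 1) {
    return(max(h[[1]]))
  }
  if (n == 2) {
    H <- outer(h[[1]], h[[2]], "+")
    feas <- if (all(top)) {
      outer(grid, grid, function(a, b) a + b <= 1 + 1e-12)
    } else {
      # one parent, one child (child listed where parent is set)
      ci <- which(!top)
      pi <- which(top)
      if (ci == 1) outer(grid, grid, function(a, b) a <= b + 1e-12)
      else outer(grid, grid, function(a, b) b <= a + 1e-12)
    }
    return(max(H[feas]))
  }
  # n == 3: enumerate over the third index to bound memory
  best <- -Inf
  H12 <- outer(h[[1]], h[[2]], "+")
  for (k in seq_along(grid)) {
    f3 <- grid[k]
    feas <- feasible_mask_3(grid, ids, parent, f3)
    if (!any(feas)) next
    val <- max(H12[feas]) + h[[3]][k]
    if (val > best) best <- val
  }
  best
}

# feasibility of (f1, f2) given f3 for three-lineage shapes: within every
# sibling group the summed child frequencies may not exceed the parent's
# (and top-level lineages may not sum past 1)
feasible_mask_3 <- function(grid, ids, parent, f3) {
  f1 <- matrix(grid, length(grid), length(grid))
  f2 <- t(f1)
  fs <- list(f1, f2, f3)
  ok <- matrix(TRUE, length(grid), length(grid))
  for (p in unique(parent[!is.na(parent)])) {
    kids <- which(!is.na(parent) & parent == p)
    s <- Reduce(`+`, fs[kids])
    ok <- ok & (s <= fs[[match(p, ids)]] + 1e-12)
  }
  top <- which(is.na(parent))
  s <- Reduce(`+`, fs[top])
  ok & (s <= 1 + 1e-12)
}

# Random <=3-lineage instance: a hierarchy shape, true feasible frequencies,
# markers, and binomially sampled counts at the given depth.
random_instance <- function(seed, depth = 100, markers_per_lineage = 6) {
  set.seed(seed)
  shape <- sample(c("single", "siblings", "parent_child", "chain", "fork"), 1)
  def <- switch(shape,
    single = list(ids = "A", parent = NA_character_),
    siblings = list(ids = c("A", "B"), parent = c(NA, NA)),
    parent_child = list(ids = c("A", "B"), parent = c(NA, "A")),
    chain = list(ids = c("A", "B", "C"), parent = c(NA, "A", "B")),
    fork = list(ids = c("A", "B", "C"), parent = c(NA, "A", "A"))
  )
  n <- length(def$ids)
  # draw a feasible truth by stick-breaking from the root down
  f <- numeric(n)
  names(f) <- def$ids
  for (i in seq_len(n)) {
    cap <- if (is.na(def$parent[i])) {
      1 - sum(f[which(is.na(def$parent[seq_len(i - 1)]))])
    } else {
      sibs <- def$ids[seq_len(i - 1)][!is.na(def$parent[seq_len(i - 1)]) &
        def$parent[seq_len(i - 1)] == def$parent[i]]
      f[[def$parent[i]]] - sum(f[sibs])
    }
    f[i] <- stats::runif(1, 0.05, 0.95) * max(cap, 0)
  }
  g_choices <- c(1 / 3, 1 / 2, 2 / 3, 1)
  markers <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      lineage = def$ids[i],
      site = sprintf("%s_m%02d", def$ids[i], seq_len(markers_per_lineage)),
      g_m = sample(g_choices, markers_per_lineage, replace = TRUE)
    )
  })
  d <- stats::rpois(nrow(markers), depth)
  p <- pmin(pmax(markers$g_m * f[markers$lineage], 0.002), 0.998)
  x <- stats::rbinom(nrow(markers), d, p)
  list(
    model = make_toy_model(
      tibble::tibble(lineage = def$ids, parent = def$parent),
      markers
    ),
    counts = make_counts(markers$site, as.integer(x), as.integer(d)),
    truth = f
  )
}

# A fixed, hand-built sim_truth with three top-level lineages and constant
# trajectories; optionally an extra fourth lineage carved out of the residual
# (so the truths of L1..L3 are identical with and without it).
make_fixed_truth <- function(with_extra = FALSE, n_timepoints = 6,
                             markers_per_lineage = 12) {
  ids <- c("L1", "L2", "L3", if (with_extra) "L4")
  n <- length(ids)
  f_base <- c(L1 = 0.45, L2 = 0.25, L3 = 0.10)
  residual <- 0.20
  f <- if (with_extra) c(f_base, L4 = 0.12) else f_base
  res <- if (with_extra) residual - 0.12 else residual
  lineages <- tibble::tibble(
    lineage = ids, parent = NA_character_, founder = ids,
    ploidy = rep(c(2L, 3L), length.out = n),
    fitness = 0, origin_step = 0L
  )
  markers <- purrr::map_dfr(seq_len(n), function(i) {
    fr <- if (lineages$ploidy[i] == 2L) c(1 / 2, 1) else c(1 / 3, 2 / 3, 1)
    tibble::tibble(
      lineage = ids[i],
      g_m = rep(fr, length.out = markers_per_lineage)
    )
  })
  n_sites <- nrow(markers)
  sites <- tibble::tibble(
    chrom = "chrI", pos = seq_len(n_sites) * 100L,
    ref = "A", alt = "T", site = site_key_test("chrI", seq_len(n_sites) * 100L)
  )
  markers$site <- sites$site
  timepoints <- (seq_len(n_timepoints) - 1) * 10
  trajectories <- tibble::tibble(
    timepoint = rep(timepoints, times = n),
    lineage = rep(ids, each = n_timepoints),
    frequency = rep(unname(f), each = n_timepoints),
    exclusive = rep(unname(f), each = n_timepoints),
    residual = res
  )
  background <- tibble::tibble(
    class = character(), carriers = list(), g_carrier = list(), site = character()
  )
  structure(
    list(
      lineages = lineages, markers = markers, background = background,
      sites = sites, trajectories = trajectories, timepoints = timepoints,
      config = sim_config(
        n_lineages = n, n_founders = n, n_timepoints = n_timepoints,
        markers_per_lineage = markers_per_lineage, n_background = 10
      ),
      seed = 0
    ),
    class = "sim_truth"
  )
}

site_key_test <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Small scaled-down season shared by several tests (cached per session).
small_season <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_season(sim_config(n_background = 600), seed = 42)
    }
    cache
  }
})

# write a tiny VCF with AD fields; returns the path
write_test_vcf <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}
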