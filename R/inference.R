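#' Expected metagenomic allele frequency of a marker
#'
#' A marker carried at copy fraction `g_m` by a lineage at genome-copy
#' frequency `F` is expected at allele frequency `g_m * F` in the
#' whole-population sample. The value is clamped to `[eps, 1 - eps]` so the
#' binomial log-likelihood stays finite at the constraint boundaries and
#' sporadic error reads at absent markers are not infinitely surprising.
#'
#' @param f lineage frequency in `[0, 1]` (vectorized).
#' @param g marker copy fraction (vectorized).
#' @param eps error floor/ceiling, in `(0, 0.5)`.
#' @return numeric vector of probabilities in `[eps, 1 - eps]`.
#' @export
expected_marker_freq <- function(f, g, eps = 0.002) {
  check_prob(f, "f")
  check_prob(eps, "eps", lo = 1e-12, hi = 0.5 - 1e-12)
  clamp(g * f, eps, 1 - eps)
}

# Marker data per lineage at one timepoint: list of (x, d, g) vectors,
# named by lineage, markers below the depth gate dropped.
marker_data_at_t <- function(model, counts, min_marker_depth) {
  joined <- dplyr::inner_join(model$markers, counts, by = "site")
  joined <- dplyr::filter(joined, .data$depth >= .env$min_marker_depth)
  split_tb <- split(joined, factor(joined$lineage, levels = model$lineages$lineage))
  lapply(split_tb, function(tb) list(x = tb$alt_count, d = tb$depth, g = tb$g_m))
}

#' Log-likelihood of a lineage frequency vector at one timepoint
#'
#' Sums, over lineages and their markers, the binomial log probability of the
#' observed alternate count given the expected marker frequency
#' ([expected_marker_freq()]). Markers with depth below `min_marker_depth`
#' are skipped. The likelihood is separable: each lineage's markers depend
#' only on that lineage's own frequency; the lineages are coupled only
#' through the nested-sum constraints enforced by the optimizer.
#'
#' @param f named numeric vector of inclusive lineage frequencies (names must
#'   cover the model's lineages).
#' @param model a `lineage_model`.
#' @param counts tibble of one metagenomic sample: columns `site`,
#'   `alt_count`, `depth`.
#' @param eps error floor (default 0.002).
#' @param min_marker_depth per-timepoint marker depth gate (default 10).
#' @return scalar log-likelihood.
#' @export
lineage_loglik <- function(f, model, counts, eps = 0.002, min_marker_depth = 10) {
  md <- marker_data_at_t(model, counts, min_marker_depth)
  if (sum(vapply(md, function(m) length(m$x), integer(1))) == 0) {
    abort("no usable markers at this timepoint")
  }
  missing_f <- setdiff(names(md), names(f))
  if (length(missing_f) > 0) {
    abort(sprintf("frequency vector lacks lineage(s): %s", paste(missing_f, collapse = ", ")))
  }
  sum(vapply(names(md), function(l) lineage_loglik_1(f[[l]], md[[l]], eps), numeric(1)))
}

lineage_loglik_1 <- function(f1, m, eps) {
  if (length(m$x) == 0) return(0)
  sum(stats::dbinom(m$x, m$d, clamp(m$g * f1, eps, 1 - eps), log = TRUE))
}

# --- nested-constraint bookkeeping -----------------------------------------

# Topologically ordered lineage ids (parents before children) and the
# sibling groups (children of NA = top level, then children of each lineage).
lineage_order <- function(lineages) {
  ids <- lineages$lineage
  parent <- lineages$parent
  depth <- integer(length(ids))
  for (i in seq_along(ids)) {
    d <- 0L
    p <- parent[i]
    while (!is.na(p)) {
      d <- d + 1L
      p <- parent[match(p, ids)]
    }
    depth[i] <- d
  }
  ord <- order(depth, ids)
  list(ids = ids[ord], parent = parent[ord], depth = depth[ord])
}

# Stick-breaking map: u in (0,1)^L -> feasible inclusive frequencies F.
# Within each sibling group (ordered as in `ord`), each child takes a
# fraction u of the parent mass not yet taken by earlier siblings, so the
# image is exactly the feasible set {0 <= F, sum(children) <= parent,
# sum(top level) <= 1}.
stick_to_freq <- function(u, ord) {
  f <- stats::setNames(numeric(length(ord$ids)), ord$ids)
  avail <- stats::setNames(numeric(length(ord$ids) + 1), c(ord$ids, ".root"))
  avail[".root"] <- 1
  for (i in seq_along(ord$ids)) {
    pid <- if (is.na(ord$parent[i])) ".root" else ord$parent[i]
    f[i] <- u[i] * avail[[pid]]
    avail[[pid]] <- avail[[pid]] - f[i]
    avail[[ord$ids[i]]] <- f[i]
  }
  f
}

# Inverse of stick_to_freq for a feasible F (used to seed the optimizer).
freq_to_stick <- function(f, ord) {
  u <- numeric(length(ord$ids))
  avail <- stats::setNames(numeric(length(ord$ids) + 1), c(ord$ids, ".root"))
  avail[".root"] <- 1
  for (i in seq_along(ord$ids)) {
    pid <- if (is.na(ord$parent[i])) ".root" else ord$parent[i]
    a <- avail[[pid]]
    u[i] <- if (a > 0) f[[ord$ids[i]]] / a else 0
    avail[[pid]] <- a - f[[ord$ids[i]]]
    avail[[ord$ids[i]]] <- f[[ord$ids[i]]]
  }
  clamp(u, 1e-7, 1 - 1e-7)
}

# Project an arbitrary F in [0,1]^L onto the feasible nested set:
# bottom-up, raise each parent to at least the sum of its children; then
# top-down, rescale sibling groups that overflow their parent mass.
make_feasible <- function(f, ord) {
  ids <- ord$ids
  for (i in rev(seq_along(ids))) {
    kids <- ids[!is.na(ord$parent) & ord$parent == ids[i]]
    if (length(kids) > 0) f[ids[i]] <- min(1, max(f[[ids[i]]], sum(f[kids])))
  }
  groups <- split(ids, ifelse(is.na(ord$parent), ".root", ord$parent))
  for (pid in names(groups)) {
    cap <- if (pid == ".root") 1 else f[[pid]]
    s <- sum(f[groups[[pid]]])
    if (s > cap && s > 0) f[groups[[pid]]] <- f[groups[[pid]]] * (cap / s)
  }
  f
}

#' Jointly infer lineage frequencies at one timepoint
#'
#' Maximizes the binomial marker log-likelihood over all inclusive lineage
#' frequencies subject to the nested constraints (each frequency in
#' `[0, 1]`; the summed frequencies of sister lineages never exceed their
#' parent's; top-level lineages sum to at most 1). The constrained problem is
#' reparameterized by stick-breaking — each lineage takes a fraction of its
#' parent's not-yet-allocated mass — turning the feasible set into a unit box
#' over which `L-BFGS-B` runs. Multi-start: one start from the pooled
#' closed-form per-lineage estimate (`sum(x) / sum(d * g)`, projected onto the
#' feasible set) and `restarts - 1` random feasible starts; the best restart
#' is returned.
#'
#' @inheritParams lineage_loglik
#' @param restarts number of optimizer starts (default 5).
#' @param seed integer seed for the random restarts (default 1).
#' @param timepoint optional timepoint label copied into the result.
#' @return a `freq_estimate` tibble, one row per lineage: `timepoint`,
#'   `lineage`, `parent`, `frequency` (inclusive), `exclusive`, `residual`,
#'   `n_markers_used`, `identifiable`. Attributes: `loglik`, `converged`,
#'   `restarts`.
#' @export
infer_frequencies <- function(model, counts, eps = 0.002, min_marker_depth = 10,
                              restarts = 5, seed = 1, timepoint = NA_real_) {
  stopifnot(restarts >= 1)
  md <- marker_data_at_t(model, counts, min_marker_depth)
  n_used <- vapply(md, function(m) length(m$x), integer(1))
  if (sum(n_used) == 0) {
    abort(sprintf(
      "no usable markers at timepoint %s (all below depth %g)",
      format(timepoint), min_marker_depth
    ))
  }
  ord <- lineage_order(model$lineages)
  md <- md[ord$ids]
  n_used <- n_used[ord$ids]

  neg_ll <- function(u) {
    f <- stick_to_freq(u, ord)
    -sum(vapply(seq_along(f), function(i) {
      lineage_loglik_1(f[[i]], md[[i]], eps)
    }, numeric(1)))
  }

  # pooled closed-form start: F ~ sum(x) / sum(d g), projected to feasibility
  f0 <- vapply(md, function(m) {
    if (length(m$x) == 0 || sum(m$d * m$g) == 0) return(0)
    clamp(sum(m$x) / sum(m$d * m$g), 0, 1)
  }, numeric(1))
  starts <- list(freq_to_stick(make_feasible(f0, ord), ord))
  if (restarts > 1) {
    rng <- local({
      set.seed(seed)
      matrix(stats::runif((restarts - 1) * length(ord$ids), 0.02, 0.98),
        nrow = restarts - 1
      )
    })
    for (i in seq_len(restarts - 1)) starts <- c(starts, list(rng[i, ]))
  }

  best <- NULL
  any_converged <- FALSE
  for (u0 in starts) {
    fit <- tryCatch(
      stats::optim(u0, neg_ll,
        method = "L-BFGS-B",
        lower = rep(1e-7, length(u0)), upper = rep(1 - 1e-7, length(u0)),
        control = list(maxit = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) abort("optimizer failed in every restart")

  # cyclic coordinate refinement: the stick-breaking map can leave gradient
  # plateaus (a parent's stick near 0 flattens all descendant coordinates);
  # exact 1-D line searches escape them cheaply
  u <- best$par
  val <- best$value
  for (sweep in 1:8) {
    improved <- FALSE
    for (j in seq_along(u)) {
      opt <- stats::optimize(function(z) {
        uz <- u
        uz[j] <- z
        neg_ll(uz)
      }, interval = c(1e-7, 1 - 1e-7), tol = 1e-8)
      if (opt$objective < val - 1e-10) {
        u[j] <- opt$minimum
        val <- opt$objective
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  best$par <- u
  best$value <- val

  f <- stick_to_freq(best$par, ord)
  # lineages with no usable markers are unidentifiable: collapse their
  # frequency to the minimum the constraints force (sum of children)
  identifiable <- n_used > 0
  for (i in rev(seq_along(ord$ids))) {
    if (!identifiable[i]) {
      kids <- ord$ids[!is.na(ord$parent) & ord$parent == ord$ids[i]]
      f[i] <- if (length(kids) > 0) sum(f[kids]) else 0
    }
  }

  kids_sum <- vapply(ord$ids, function(id) {
    sum(f[ord$ids[!is.na(ord$parent) & ord$parent == id]])
  }, numeric(1))
  exclusive <- pmax(f - kids_sum, 0)
  residual <- max(1 - sum(f[is.na(ord$parent)]), 0)

  out <- tibble::tibble(
    timepoint = timepoint,
    lineage = ord$ids,
    parent = ord$parent,
    frequency = unname(f),
    exclusive = unname(exclusive),
    residual = residual,
    n_markers_used = unname(n_used),
    identifiable = unname(identifiable)
  )
  out <- tibble::new_tibble(out, class = "freq_estimate")
  attr(out, "loglik") <- -best$value
  attr(out, "converged") <- any_converged
  attr(out, "restarts") <- length(starts)
  out
}

#' Infer lineage frequency trajectories across a metagenomic time series
#'
#' Runs [infer_frequencies()] at each metagenomic timepoint independently —
#' no information is shared or smoothed across timepoints, so the estimates
#' at different times are independent given the model. Per-timepoint
#' failures (e.g. no usable markers) are reported in the result, leaving the
#' other timepoints unaffected.
#'
#' @inheritParams infer_frequencies
#' @param vm long variant tibble containing the metagenome samples.
#' @param sheet sample sheet tibble ([read_sample_sheet()]); rows with
#'   `role == "metagenome"` define the series.
#' @param seed master seed; each timepoint's restarts are seeded from it and
#'   from the timepoint value (not its position), so estimates do not depend
#'   on input ordering.
#' @return a `lineage_trajectories` tibble: the row-bound per-timepoint
#'   estimates with columns `timepoint`, `sample`, `lineage`, `parent`,
#'   `frequency`, `exclusive`, `residual`, `n_markers_used`, `identifiable`,
#'   `converged`, `loglik`, ordered by time. Attribute `failures` is a tibble
#'   of timepoints that could not be estimated.
#' @export
infer_trajectories <- function(model, vm, sheet, eps = 0.002,
                               min_marker_depth = 10, restarts = 5, seed = 1) {
  meta <- dplyr::arrange(
    dplyr::filter(validate_sample_sheet(sheet), .data$role == "metagenome"),
    .data$timepoint_days
  )
  if (nrow(meta) == 0) abort("sample sheet contains no metagenome samples")
  missing_samples <- setdiff(meta$sample, unique(vm$sample))
  if (length(missing_samples) > 0) {
    abort(sprintf(
      "metagenome sample(s) absent from variant table: %s",
      paste(missing_samples, collapse = ", ")
    ))
  }
  failures <- list()
  rows <- purrr::map(seq_len(nrow(meta)), function(i) {
    s <- meta$sample[i]
    t <- meta$timepoint_days[i]
    counts <- dplyr::select(
      dplyr::filter(vm, .data$sample == s), "site", "alt_count", "depth"
    )
    est <- tryCatch(
      infer_frequencies(model, counts,
        eps = eps, min_marker_depth = min_marker_depth, restarts = restarts,
        seed = (abs(seed) + round(t * 997)) %% 2147483629, timepoint = t
      ),
      error = function(e) e
    )
    if (inherits(est, "error")) {
      failures[[length(failures) + 1]] <<- tibble::tibble(
        timepoint = t, sample = s, error = conditionMessage(est)
      )
      return(NULL)
    }
    est$sample <- s
    est$converged <- attr(est, "converged")
    est$loglik <- attr(est, "loglik")
    est
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no timepoint could be estimated")
  out <- dplyr::relocate(out, "timepoint", "sample", "lineage")
  out <- tibble::new_tibble(out, class = "lineage_trajectories")
  attr(out, "failures") <- dplyr::bind_rows(failures)
  attr(out, "lineages") <- model$lineages
  out
}

#' Exclusive frequencies and residual of a frequency estimate
#'
#' Recomputes, per timepoint, each lineage's exclusive frequency
#' `E = F - sum(children F)` and the residual `R = 1 - sum(top-level F)` (the
#' population fraction not represented by any tracked lineage), checking the
#' nested-sum invariants to a 1e-6 tolerance. The exclusive frequencies plus
#' the residual sum to 1 at every timepoint.
#'
#' @param estimates a `freq_estimate` or `lineage_trajectories` tibble.
#' @param tol constraint tolerance (default 1e-6).
#' @return tibble `timepoint`, `lineage`, `frequency`, `exclusive`,
#'   `residual`.
#' @export
exclusive_frequencies <- function(estimates, tol = 1e-6) {
  purrr::map_dfr(split(estimates, estimates$timepoint), function(tb) {
    f <- stats::setNames(tb$frequency, tb$lineage)
    kids_sum <- vapply(tb$lineage, function(id) {
      sum(f[tb$lineage[!is.na(tb$parent) & tb$parent == id]])
    }, numeric(1))
    e <- f - kids_sum
    r <- 1 - sum(f[is.na(tb$parent)])
    if (any(e < -tol) || r < -tol || any(f < -tol | f > 1 + tol)) {
      abort(sprintf(
        "nested-sum constraints violated beyond tolerance at timepoint %s",
        format(tb$timepoint[1])
      ))
    }
    tibble::tibble(
      timepoint = tb$timepoint, lineage = tb$lineage,
      frequency = unname(f), exclusive = pmax(unname(e), 0),
      residual = max(r, 0)
    )
  })
}

#' Convert genome-copy fractions to cell fractions
#'
#' Metagenomic reads measure genome copies, so a triploid lineage at cell
#' fraction `c` contributes 1.5 times the DNA of a diploid at the same cell
#' fraction. This post-hoc converter divides each lineage's exclusive
#' genome-copy fraction by its ploidy and renormalizes (the residual is
#' assigned `residual_ploidy`, default 2). It is intentionally not applied by
#' default: DNA fractions are what the reads measure.
#'
#' @param estimates `lineage_trajectories` (or compatible) tibble.
#' @param ploidy_by_lineage named numeric vector: ploidy per lineage.
#' @param residual_ploidy ploidy assumed for the untracked residual mass.
#' @return the input with an added `cell_fraction` column (exclusive cell
#'   fractions; residual rows are not added, but the renormalization accounts
#'   for the residual mass).
#' @export
as_cell_fractions <- function(estimates, ploidy_by_lineage, residual_ploidy = 2) {
  missing_pl <- setdiff(unique(estimates$lineage), names(ploidy_by_lineage))
  if (length(missing_pl) > 0) {
    abort(sprintf("no ploidy given for lineage(s): %s", paste(missing_pl, collapse = ", ")))
  }
  purrr::map_dfr(split(estimates, estimates$timepoint), function(tb) {
    w <- tb$exclusive / ploidy_by_lineage[tb$lineage]
    w_res <- tb$residual[1] / residual_ploidy
    tb$cell_fraction <- as.numeric(w / (sum(w) + w_res))
    tb
  })
}
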