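#' Enumerate the clades of a rooted clone phylogeny
#'
#' Every internal node and every tip defines a candidate lineage: the set of
#' isolates descending from it. The root clade is the full tip set; tips give
#' singleton lineages (allowed, but flagged downstream since their markers
#' may include clone-private artifacts).
#'
#' @param tree a rooted `phylo` object whose tips are clone identifiers.
#' @param clones optional character vector of genotyped clones; tips absent
#'   from it raise an error naming the offenders.
#' @return a named list of character vectors (tip sets), one per clade,
#'   ordered root-first by decreasing size. Names are stable clade ids.
#' @export
enumerate_clades <- function(tree, clones = NULL) {
  validate_tree(tree)
  tips <- tree$tip.label
  if (!is.null(clones)) {
    extra <- setdiff(tips, clones)
    if (length(extra) > 0) {
      abort(sprintf(
        "tree tip(s) absent from genotype data: %s", paste(extra, collapse = ", ")
      ))
    }
  }
  n_tip <- length(tips)
  clades <- list()
  if (n_tip > 1) {
    pp <- ape::prop.part(tree)
    clades <- lapply(pp, function(idx) tips[idx])
  }
  clades <- c(clades, as.list(tips))
  sizes <- vapply(clades, length, integer(1))
  clades <- clades[order(-sizes, vapply(clades, function(x) paste(sort(x), collapse = "|"), ""))]
  clades <- clades[!duplicated(vapply(clades, function(x) paste(sort(x), collapse = "|"), ""))]
  names(clades) <- sprintf("clade_%02d", seq_along(clades))
  clades
}

#' Find the synapomorphic markers of one clade
#'
#' A site is a synapomorphic marker of a clade when (i) every non-missing
#' member carries the alternate allele at one identical copy fraction
#' `g > 0`, (ii) every non-missing non-member has `g = 0`, and (iii) the
#' missing-call fraction among members and among non-members is each at most
#' `max_missing_frac`. Markers are polarized on the alternate allele only:
#' sites whose shared state would be the reference allele are not usable.
#' The shared copy fraction `g_m` must be constant across members so that the
#' marker's expected metagenomic allele frequency is `g_m` times the lineage
#' frequency.
#'
#' @param clade character vector of member clone ids.
#' @param genotypes `clone_genotypes` tibble or a genotype matrix
#'   ([genotype_matrix()]).
#' @param max_missing_frac maximum tolerated missing-call fraction within
#'   members and within non-members (default 0.2).
#' @param min_markers minimum marker count for the clade to be trackable
#'   (default 10).
#' @return a list: `markers` (tibble `site`, `g_m`; empty if rejected),
#'   `reason` (`NA` if accepted).
#' @export
find_synapomorphies <- function(clade, genotypes, max_missing_frac = 0.2,
                                min_markers = 10) {
  G <- if (is.matrix(genotypes)) genotypes else genotype_matrix(genotypes)
  missing_members <- setdiff(clade, rownames(G))
  if (length(missing_members) > 0) {
    abort(sprintf(
      "clade member(s) not in genotype matrix: %s",
      paste(missing_members, collapse = ", ")
    ))
  }
  flags <- synapomorphy_flags(G, rownames(G) %in% clade, max_missing_frac)
  markers <- tibble::tibble(site = colnames(G)[flags$ok], g_m = flags$g_m[flags$ok])
  if (nrow(markers) < min_markers) {
    return(list(
      markers = markers[0, ],
      reason = sprintf("only %d qualifying marker(s), need %d", nrow(markers), min_markers)
    ))
  }
  list(markers = markers, reason = NA_character_)
}

# Vectorized synapomorphy test over all sites for one member mask.
# Returns ok (logical per site) and g_m (shared member copy fraction).
synapomorphy_flags <- function(G, is_member, max_missing_frac) {
  Gm <- G[is_member, , drop = FALSE]
  Go <- G[!is_member, , drop = FALSE]
  n_m <- nrow(Gm)
  n_o <- nrow(Go)

  col_max <- function(M, fill) {
    if (nrow(M) == 0) return(rep(fill, ncol(M)))
    v <- do.call(pmax, c(lapply(seq_len(nrow(M)), function(i) M[i, ]), na.rm = TRUE))
    v[is.na(v)] <- fill
    v
  }
  col_min <- function(M, fill) {
    if (nrow(M) == 0) return(rep(fill, ncol(M)))
    v <- do.call(pmin, c(lapply(seq_len(nrow(M)), function(i) M[i, ]), na.rm = TRUE))
    v[is.na(v)] <- fill
    v
  }
  miss_m <- colSums(is.na(Gm)) / max(n_m, 1)
  obs_m <- n_m - colSums(is.na(Gm))
  gmax <- col_max(Gm, fill = -Inf)
  gmin <- col_min(Gm, fill = Inf)
  members_ok <- obs_m > 0 & is.finite(gmax) & gmax == gmin & gmax > 0

  if (n_o > 0) {
    miss_o <- colSums(is.na(Go)) / n_o
    outside_ok <- col_max(Go, fill = 0) == 0
  } else {
    miss_o <- rep(0, ncol(G))
    outside_ok <- rep(TRUE, ncol(G))
  }
  ok <- members_ok & outside_ok &
    miss_m <= max_missing_frac & miss_o <= max_missing_frac
  list(ok = unname(ok), g_m = unname(gmax))
}

#' Build a lineage model from a clone phylogeny and genotype calls
#'
#' Enumerates the clades of the tree, finds each clade's synapomorphic
#' markers, keeps clades with at least `min_markers` of them, and arranges
#' the kept clades into the nested lineage hierarchy used by the frequency
#' inference. Each marker site is assigned to exactly one lineage; in the
#' rare case that a site qualifies for more than one kept clade (possible
#' only through missing calls), it is assigned to the smallest such clade.
#' Clades failing the marker rules are recorded with their reasons, as are
#' sites matching no clean clade pattern (homoplasies).
#'
#' @inheritParams find_synapomorphies
#' @param tree rooted `phylo` of the clones.
#' @return a `lineage_model` object: list with tibbles `lineages` (`lineage`,
#'   `parent`, `n_members`, `n_markers`, `singleton`, list-column `members`),
#'   `markers` (`lineage`, `site`, `g_m`), `discarded` (`clade`, `members`,
#'   `reason`), plus `tree`, `clones` and the genotype matrix.
#' @export
build_lineage_model <- function(tree, genotypes, min_markers = 10,
                                max_missing_frac = 0.2) {
  G <- if (is.matrix(genotypes)) genotypes else genotype_matrix(genotypes)
  clades <- enumerate_clades(tree, clones = rownames(G))

  scan <- purrr::map(clades, function(cl) {
    synapomorphy_flags(G, rownames(G) %in% cl, max_missing_frac)
  })
  n_sites <- ncol(G)
  qual <- vapply(scan, function(s) s$ok, logical(n_sites))
  qual <- matrix(qual, nrow = n_sites, dimnames = list(colnames(G), names(clades)))

  clade_size <- vapply(clades, length, integer(1))
  # assign each qualifying site to the smallest qualifying clade
  assign_idx <- apply(qual, 1, function(row) {
    hits <- which(row)
    if (length(hits) == 0) return(NA_integer_)
    hits[which.min(clade_size[hits])]
  })

  marker_tb <- tibble::tibble(
    site = colnames(G),
    clade = names(clades)[assign_idx],
    g_m = vapply(seq_len(n_sites), function(i) {
      if (is.na(assign_idx[i])) NA_real_ else scan[[assign_idx[i]]]$g_m[i]
    }, numeric(1))
  )
  counts <- table(factor(marker_tb$clade, levels = names(clades)))
  keep <- names(clades)[counts >= min_markers]
  if (length(keep) == 0) {
    abort("no trackable lineages: no clade reaches the minimum marker count")
  }

  kept_sets <- clades[keep]
  # parent = smallest kept clade strictly containing this one
  parent_of <- vapply(keep, function(id) {
    me <- kept_sets[[id]]
    sup <- keep[vapply(keep, function(other) {
      o <- kept_sets[[other]]
      length(o) > length(me) && all(me %in% o)
    }, logical(1))]
    if (length(sup) == 0) return(NA_character_)
    sup[which.min(clade_size[sup])]
  }, character(1))

  lineages <- tibble::tibble(
    lineage = keep,
    parent = parent_of,
    n_members = clade_size[keep],
    n_markers = as.integer(counts[keep]),
    singleton = clade_size[keep] == 1L,
    members = unname(kept_sets)
  )
  markers <- dplyr::filter(marker_tb, .data$clade %in% keep)
  markers <- tibble::tibble(lineage = markers$clade, site = markers$site, g_m = markers$g_m)

  discarded_ids <- setdiff(names(clades), keep)
  discarded <- tibble::tibble(
    clade = discarded_ids,
    members = unname(clades[discarded_ids]),
    reason = sprintf(
      "only %d qualifying marker(s), need %d",
      as.integer(counts[discarded_ids]), min_markers
    )
  )
  unassigned <- marker_tb$site[is.na(marker_tb$clade)]

  structure(
    list(
      lineages = lineages, markers = markers, discarded = discarded,
      unassigned_sites = unassigned, tree = tree, clones = rownames(G),
      genotype_matrix = G,
      rules = list(min_markers = min_markers, max_missing_frac = max_missing_frac)
    ),
    class = "lineage_model"
  )
}

#' @export
#' @method print lineage_model
print.lineage_model <- function(x, ...) {
  cat(sprintf(
    "<lineage_model> %d lineages from %d clones; %d markers assigned, %d sites unassigned\n",
    nrow(x$lineages), length(x$clones), nrow(x$markers), length(x$unassigned_sites)
  ))
  print(dplyr::select(x$lineages, -"members"), ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname build_lineage_model
#' @param x a `lineage_model`.
#' @param ... unused.
#' @export
tidy.lineage_model <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(x$lineages, -"members"),
    members = vapply(x$lineages$members, paste, collapse = ",", FUN.VALUE = "")
  )
}

#' @rdname build_lineage_model
#' @export
glance.lineage_model <- function(x, ...) {
  tibble::tibble(
    n_lineages = nrow(x$lineages),
    n_clones = length(x$clones),
    n_markers = nrow(x$markers),
    n_unassigned_sites = length(x$unassigned_sites),
    n_discarded_clades = nrow(x$discarded)
  )
}

#' Neighbor-joining tree from genotype calls (convenience plumbing)
#'
#' Builds an unsupported starting tree for users without a phylogeny, from
#' pairwise mean absolute differences in copy fraction between clones
#' (missing calls pairwise-deleted), via [ape::nj()]. Not a substitute for a
#' proper maximum-likelihood phylogeny.
#'
#' @inheritParams genotype_matrix
#' @return a rooted `phylo` (midpoint-free; rooted arbitrarily at the first
#'   clone's outgroupless NJ root as returned by `ape`).
#' @export
nj_genotype_tree <- function(genotypes) {
  G <- if (is.matrix(genotypes)) genotypes else genotype_matrix(genotypes)
  if (nrow(G) < 3) abort("need at least 3 clones for a neighbor-joining tree")
  D <- as.matrix(stats::dist(G, method = "manhattan")) / ncol(G)
  tree <- ape::nj(stats::as.dist(D))
  validate_tree(tree)
}
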