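#' Cross-validate pipeline inputs without running inference
#'
#' Checks name/role/timepoint consistency across the variant table, sample
#' sheet and clone tree and returns a machine-readable report; problems are
#' listed, never raised.
#'
#' @param vm long variant tibble.
#' @param sheet sample sheet tibble.
#' @param tree optional clone `phylo`.
#' @return tibble of problems (`check`, `detail`); zero rows when consistent.
#' @export
validate_inputs <- function(vm, sheet, tree = NULL) {
  problems <- list()
  note <- function(check, detail) {
    problems[[length(problems) + 1]] <<- tibble::tibble(check = check, detail = detail)
  }
  sheet_ok <- tryCatch(
    {
      validate_sample_sheet(sheet)
      TRUE
    },
    error = function(e) {
      note("sample_sheet", conditionMessage(e))
      FALSE
    }
  )
  vm_samples <- unique(vm$sample)
  if (sheet_ok) {
    for (s in setdiff(sheet$sample, vm_samples)) {
      note("sample_missing_from_variants", s)
    }
    meta <- sheet[sheet$role == "metagenome", ]
    if (nrow(meta) == 0) note("no_metagenome_samples", "sample sheet lists no metagenome samples")
    if (sum(sheet$role %in% c("clone", "starter")) == 0) {
      note("no_clone_samples", "sample sheet lists no clone samples")
    }
  }
  if (!is.null(tree)) {
    clones <- if (sheet_ok) sheet$sample[sheet$role %in% c("clone", "starter")] else vm_samples
    for (tip in setdiff(tree$tip.label, clones)) {
      note("tree_tip_not_a_clone", tip)
    }
    for (tip in setdiff(tree$tip.label, vm_samples)) {
      note("tree_tip_missing_from_variants", tip)
    }
  }
  if (length(problems) == 0) {
    tibble::tibble(check = character(), detail = character())
  } else {
    dplyr::bind_rows(problems)
  }
}

#' Run the full lineage-tracking pipeline
#'
#' Executes ploidy calling, genotyping, lineage-model construction and
#' per-timepoint frequency inference, writing every stage's tables plus run
#' metadata to `outdir`. Stages run in order; a stage failure aborts the
#' downstream stages with a message naming the stage. Outputs are written
#' atomically per stage (to a temporary name, then renamed), so a partial
#' failure never leaves a silently truncated frequency table. The master
#' seed fans out to fixed per-stage seeds, so any stage can be rerun in
#' isolation reproducibly.
#'
#' @param vm long variant tibble with both clone and metagenome samples (or a
#'   path readable by [read_variant_table()]).
#' @param sheet sample sheet tibble or TSV path.
#' @param tree clone phylogeny (`phylo` or Newick path).
#' @param outdir output directory (created if needed).
#' @param params named list overriding defaults: `min_depth_ploidy`,
#'   `min_sites_ploidy`, `min_depth_genotype`, `posterior_threshold`,
#'   `error_rate`, `min_markers`, `max_missing_frac`, `eps`,
#'   `min_marker_depth`, `restarts`.
#' @param seed master seed (default 1), recorded in the run metadata.
#' @return (invisibly) a list with the in-memory stage results: `ploidy`,
#'   `genotypes`, `model`, `trajectories`, `outdir`.
#' @export
run_pipeline <- function(vm, sheet, tree, outdir, params = list(), seed = 1) {
  if (is.character(vm)) vm <- read_variant_table(vm)
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(tree)) tree <- read_newick(tree)
  p <- utils::modifyList(list(
    min_depth_ploidy = 10, min_sites_ploidy = 50,
    min_depth_genotype = 8, posterior_threshold = 0.95, error_rate = 0.005,
    min_markers = 10, max_missing_frac = 0.2,
    eps = 0.002, min_marker_depth = 10, restarts = 5
  ), params)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  write_atomic <- function(write_fun, obj, name) {
    tmp <- file.path(outdir, paste0(".", name, ".tmp"))
    write_fun(obj, tmp)
    file.rename(tmp, file.path(outdir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  vm <- stage("ingest", filter_biallelic_snps(validate_variants(vm)))
  sheet <- stage("ingest", validate_sample_sheet(sheet))
  clones <- sheet$sample[sheet$role %in% c("clone", "starter")]
  clone_vm <- dplyr::filter(vm, .data$sample %in% clones)

  ploidy <- stage("ploidy", call_ploidies(clone_vm, clones,
    min_depth = p$min_depth_ploidy, error_rate = p$error_rate,
    min_sites = p$min_sites_ploidy
  ))
  write_atomic(function(x, f) readr::write_tsv(x, f, progress = FALSE), ploidy, "ploidy.tsv")

  genotypes <- stage("genotype", call_genotypes(clone_vm, ploidy,
    min_depth = p$min_depth_genotype,
    posterior_threshold = p$posterior_threshold, error_rate = p$error_rate
  ))
  write_atomic(write_genotype_table, genotypes, "genotypes.tsv")

  # clones excluded at genotyping (unknown ploidy) are pruned from the tree
  genotyped <- unique(genotypes$clone)
  tree_used <- if (length(setdiff(tree$tip.label, genotyped)) > 0) {
    ape::keep.tip(tree, intersect(tree$tip.label, genotyped))
  } else {
    tree
  }
  model <- stage("lineages", build_lineage_model(tree_used, genotypes,
    min_markers = p$min_markers, max_missing_frac = p$max_missing_frac
  ))
  write_atomic(function(x, f) readr::write_tsv(tidy(x), f, progress = FALSE),
    model, "lineages.tsv"
  )
  write_atomic(function(x, f) readr::write_tsv(x$markers, f, progress = FALSE),
    model, "markers.tsv"
  )

  trajectories <- stage("infer", infer_trajectories(model, vm, sheet,
    eps = p$eps, min_marker_depth = p$min_marker_depth,
    restarts = p$restarts, seed = derive_seed(seed, "infer")
  ))
  write_atomic(write_frequency_table, trajectories, "frequencies.tsv")

  diagnostics <- list(
    failures = attr(trajectories, "failures"),
    converged = all(trajectories$converged),
    n_lineages = nrow(model$lineages),
    n_markers = nrow(model$markers)
  )
  write_atomic(
    function(x, f) jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA),
    diagnostics, "diagnostics.json"
  )
  cfg_file <- tempfile()
  writeLines(jsonlite::toJSON(p, auto_unbox = TRUE), cfg_file)
  metadata <- list(
    tool = "lineagetrace",
    version = as.character(utils::packageVersion("lineagetrace")),
    seed = seed,
    params = p,
    config_hash = unname(tools::md5sum(cfg_file))
  )
  unlink(cfg_file)
  write_atomic(
    function(x, f) jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA),
    metadata, "run_metadata.json"
  )
  invisible(list(
    ploidy = ploidy, genotypes = genotypes, model = model,
    trajectories = trajectories, outdir = outdir
  ))
}
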