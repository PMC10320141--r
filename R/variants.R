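#' Read a variant table with per-sample allele counts
#'
#' Reads biallelic-SNP-style variant data into a long tibble with one row per
#' site and sample, carrying the alternate-allele read count and the total
#' depth (reference + alternate counts). Two dialects are supported:
#'
#' * `"vcf"`: a VCF (v4.x) file whose genotype columns carry an `AD` field
#'   with comma-separated per-allele read counts, as emitted by common
#'   haplotype-based callers. Depth is defined as the sum of the `AD` entries
#'   and the alternate count as the sum over alternate alleles (multi-allelic
#'   records survive reading and are removed by [filter_biallelic_snps()]).
#' * `"tsv"`: a tab-separated long table with columns
#'   `chrom`, `pos`, `ref`, `alt`, `sample`, `alt_count`, `depth`.
#'
#' Samples with a missing or unparseable `AD` entry at a site get `depth = 0`
#' there; such entries are retained (allele frequency undefined, treated as
#' masked downstream), never imputed as zero frequency.
#'
#' @param path path to the input file.
#' @param dialect `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @return a tibble with columns `chrom`, `pos`, `ref`, `alt`, `site`,
#'   `sample`, `alt_count`, `depth`. `site` is `"chrom:pos"`. Site order of
#'   the file is preserved (rows are sorted by site appearance, then sample).
#' @export
read_variant_table <- function(path, dialect = c("auto", "vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  vm <- switch(dialect,
    vcf = read_variants_vcf(path),
    tsv = read_variants_tsv(path)
  )
  validate_variants(vm)
}

read_variants_tsv <- function(path) {
  cols <- readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    sample = readr::col_character(),
    alt_count = readr::col_integer(),
    depth = readr::col_integer()
  )
  if (file.size(path) == 0) {
    return(empty_variants())
  }
  tb <- readr::read_tsv(path, col_types = cols, progress = FALSE)
  missing_cols <- setdiff(names(cols$cols), names(tb))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "variant TSV %s lacks required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ))
  }
  tb$site <- site_key(tb$chrom, tb$pos)
  dplyr::select(
    tb, "chrom", "pos", "ref", "alt", "site", "sample", "alt_count", "depth"
  )
}

read_variants_vcf <- function(path) {
  if (file.size(path) == 0) return(empty_variants())
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) return(empty_variants())
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  pos <- suppressWarnings(as.integer(fix$POS))
  if (any(is.na(pos))) {
    bad <- which(is.na(pos))[1]
    abort(sprintf(
      "malformed coordinate at VCF record %d (POS = '%s')", bad, fix$POS[bad]
    ))
  }
  fmt <- vcf@gt[, 1, drop = TRUE]
  has_ad <- vapply(
    strsplit(fmt, ":", fixed = TRUE),
    function(f) "AD" %in% f, logical(1)
  )
  if (!all(has_ad)) {
    abort(sprintf(
      "VCF %s: %d record(s) lack an AD genotype field; per-allele depths are required",
      path, sum(!has_ad)
    ))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(ad)
  n_site <- nrow(ad)

  parse_ad <- function(v) {
    # rows: ref count, summed alt count, depth; NA/"." -> masked (depth 0)
    out <- matrix(0L, nrow = 3, ncol = length(v))
    ok <- !is.na(v) & v != "." & v != ""
    if (any(ok)) {
      parts <- strsplit(v[ok], ",", fixed = TRUE)
      ref_n <- vapply(parts, function(p) suppressWarnings(as.integer(p[1])), integer(1))
      alt_n <- vapply(parts, function(p) {
        a <- suppressWarnings(as.integer(p[-1]))
        if (length(a) == 0 || anyNA(a)) NA_integer_ else sum(a)
      }, integer(1))
      good <- !is.na(ref_n) & !is.na(alt_n)
      idx <- which(ok)[good]
      out[1, idx] <- ref_n[good]
      out[2, idx] <- alt_n[good]
      out[3, idx] <- ref_n[good] + alt_n[good]
    }
    out
  }

  long <- purrr::map_dfr(seq_along(samples), function(j) {
    m <- parse_ad(ad[, j])
    tibble::tibble(
      row = seq_len(n_site),
      sample = samples[j],
      alt_count = m[2, ],
      depth = m[3, ]
    )
  })
  sites <- tibble::tibble(
    row = seq_len(n_site),
    chrom = fix$CHROM,
    pos = pos,
    ref = fix$REF,
    alt = fix$ALT,
    site = site_key(fix$CHROM, pos)
  )
  out <- dplyr::inner_join(sites, long, by = "row")
  out <- dplyr::arrange(out, .data$row, .data$sample)
  dplyr::select(out, -"row")
}

empty_variants <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(), alt = character(),
    site = character(), sample = character(),
    alt_count = integer(), depth = integer()
  )
}

validate_variants <- function(vm) {
  if (nrow(vm) == 0) return(vm)
  if (any(vm$pos < 1, na.rm = TRUE)) abort("variant positions must be >= 1")
  bad <- which(vm$alt_count > vm$depth | vm$alt_count < 0 | vm$depth < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid counts at %s (sample %s): alt_count must satisfy 0 <= x <= depth",
      vm$site[bad[1]], vm$sample[bad[1]]
    ))
  }
  vm
}

#' Keep only biallelic single-nucleotide variant sites
#'
#' Retains sites whose reference allele is a single base and that carry
#' exactly one alternate allele, itself a single base. Multi-allelic sites
#' are dropped entirely rather than split into pseudo-biallelic records, and
#' indels are dropped. Idempotent; never adds sites.
#'
#' @param vm a long variant tibble from [read_variant_table()].
#' @param alt_alleles optional per-site alternate-allele lists (a character
#'   vector or list aligned to `unique(vm$site)`, each entry the alleles at
#'   that site, comma-separated if a vector). Defaults to splitting `vm$alt`
#'   on commas, which matches VCF `ALT` encoding.
#' @return the filtered tibble, site order preserved.
#' @export
filter_biallelic_snps <- function(vm, alt_alleles = NULL) {
  if (nrow(vm) == 0) return(vm)
  sites <- dplyr::distinct(vm, .data$site, .data$ref, .data$alt)
  if (is.null(alt_alleles)) {
    alt_list <- strsplit(sites$alt, ",", fixed = TRUE)
  } else {
    if (length(alt_alleles) != nrow(sites)) {
      abort(sprintf(
        "alt_alleles has %d entries but the table has %d sites",
        length(alt_alleles), nrow(sites)
      ))
    }
    alt_list <- if (is.list(alt_alleles)) alt_alleles else {
      strsplit(as.character(alt_alleles), ",", fixed = TRUE)
    }
  }
  keep <- vapply(alt_list, length, integer(1)) == 1L &
    nchar(sites$ref) == 1L &
    vapply(alt_list, function(a) nchar(a[1]) == 1L, logical(1)) &
    vapply(seq_along(alt_list), function(i) alt_list[[i]][1] != sites$ref[i], logical(1))
  dplyr::filter(vm, .data$site %in% sites$site[keep])
}

#' Write a long variant table to TSV
#'
#' Inverse of the `"tsv"` dialect of [read_variant_table()].
#'
#' @param vm long variant tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vm, path) {
  readr::write_tsv(
    dplyr::select(vm, "chrom", "pos", "ref", "alt", "sample", "alt_count", "depth"),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet maps sequencing samples to their role in the study design:
#' `clone` (an isolated colony), `metagenome` (a whole-population timepoint
#' sample) or `starter` (an industrial inoculum isolate). Columns: `sample`,
#' `role`, `site_year`, `timepoint_days` (days since season start; required
#' for metagenome samples), plus optional free-text `note`.
#'
#' @param path TSV path.
#' @return tibble with the columns above.
#' @export
read_sample_sheet <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    role = readr::col_character(),
    site_year = readr::col_character(),
    timepoint_days = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_sample_sheet(tb)
}

validate_sample_sheet <- function(tb) {
  need <- c("sample", "role", "site_year", "timepoint_days")
  missing_cols <- setdiff(need, names(tb))
  if (length(missing_cols) > 0) {
    abort(sprintf("sample sheet lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tb$sample)) {
    abort(sprintf(
      "duplicate sample identifier(s): %s",
      paste(unique(tb$sample[duplicated(tb$sample)]), collapse = ", ")
    ))
  }
  bad_role <- setdiff(unique(tb$role), c("clone", "metagenome", "starter"))
  if (length(bad_role) > 0) {
    abort(sprintf("unknown sample role(s): %s", paste(bad_role, collapse = ", ")))
  }
  meta <- tb[tb$role == "metagenome", ]
  if (any(is.na(meta$timepoint_days))) {
    abort(sprintf(
      "metagenome sample(s) without a timepoint: %s",
      paste(meta$sample[is.na(meta$timepoint_days)], collapse = ", ")
    ))
  }
  if (any(tb$timepoint_days < 0, na.rm = TRUE)) abort("timepoints must be non-negative")
  tb
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(validate_sample_sheet(sheet), path, progress = FALSE)
  invisible(path)
}

#' Write and re-read lineage frequency tables
#'
#' The frequency table is the pipeline's main output: one row per timepoint
#' and lineage with the inclusive frequency (the lineage plus all nested
#' sublineages), the exclusive frequency (inclusive minus the summed
#' inclusive frequencies of child lineages) and the per-timepoint residual
#' (population fraction not assigned to any top-level lineage). Values are
#' written with six decimals, so a write/read round trip is lossless at 1e-6.
#'
#' @param estimates a trajectory tibble from [infer_trajectories()] (or any
#'   tibble with columns `timepoint`, `lineage`, `frequency`, `exclusive`,
#'   `residual`).
#' @param path output TSV path.
#' @return `path` invisibly (`write_frequency_table`); a tibble
#'   (`read_frequency_table`).
#' @export
write_frequency_table <- function(estimates, path) {
  need <- c("timepoint", "lineage", "frequency", "exclusive", "residual")
  missing_cols <- setdiff(need, names(estimates))
  if (length(missing_cols) > 0) {
    abort(sprintf("frequency table lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  per_t <- split(estimates$lineage, estimates$timepoint)
  if (length(per_t) > 1) {
    ref <- sort(per_t[[1]])
    same <- vapply(per_t, function(l) identical(sort(l), ref), logical(1))
    if (!all(same)) abort("inconsistent lineage sets across timepoints")
  }
  out <- dplyr::transmute(
    estimates,
    timepoint = .data$timepoint,
    lineage = .data$lineage,
    frequency = sprintf("%.6f", .data$frequency),
    exclusive = sprintf("%.6f", .data$exclusive),
    residual = sprintf("%.6f", .data$residual)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    timepoint = readr::col_double(),
    lineage = readr::col_character(),
    frequency = readr::col_double(),
    exclusive = readr::col_double(),
    residual = readr::col_double()
  ), progress = FALSE)
}
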