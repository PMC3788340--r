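#' Load and validate a parcellation table
#'
#' The parcellation assigns each network node a ROI index, region name,
#' abbreviation, hemisphere and lobe. The bundled default is the 110-region
#' (55 per hemisphere) Harvard-Oxford-style cortical + subcortical
#' parcellation, brainstem excluded.
#'
#' @param path Path to a TSV with columns `roi_index`, `region_name`,
#'   `abbreviation`, `hemisphere`, `lobe`; defaults to the bundled table.
#' @param n_expected Expected row count (default 110); `NULL` skips the
#'   size/hemisphere-balance checks.
#' @return A validated data.frame sorted by `roi_index`.
#' @export
load_parcellation <- function(path = NULL, n_expected = 110) {
  if (is.null(path)) {
    path <- system.file("extdata", "parcellation_hoa110.tsv",
                        package = "netsweep", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0),
                           colClasses = c(roi_index = "integer"))
  required <- c("roi_index", "region_name", "abbreviation", "hemisphere", "lobe")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop(sprintf("parcellation is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(tab$roi_index)) {
    dup <- tab$roi_index[duplicated(tab$roi_index)][1]
    stop(sprintf("duplicate ROI index %d in parcellation", dup), call. = FALSE)
  }
  bad_hemi <- which(!tab$hemisphere %in% c("L", "R"))
  if (length(bad_hemi) > 0) {
    stop(sprintf("row %d: unknown hemisphere '%s'", bad_hemi[1],
                 tab$hemisphere[bad_hemi[1]]), call. = FALSE)
  }
  lobes <- c("frontal", "temporal", "parietal", "occipital", "subcortical")
  bad_lobe <- which(!tab$lobe %in% lobes)
  if (length(bad_lobe) > 0) {
    stop(sprintf("row %d: unknown lobe '%s'", bad_lobe[1],
                 tab$lobe[bad_lobe[1]]), call. = FALSE)
  }
  if (!is.null(n_expected)) {
    if (nrow(tab) != n_expected) {
      stop(sprintf("parcellation has %d rows; expected %d", nrow(tab),
                   n_expected), call. = FALSE)
    }
    n_l <- sum(tab$hemisphere == "L")
    if (n_l != n_expected / 2) {
      stop(sprintf("parcellation has %d left-hemisphere rows; expected %g",
                   n_l, n_expected / 2), call. = FALSE)
    }
    if (!setequal(tab$roi_index, seq_len(n_expected))) {
      stop(sprintf("ROI indices must be exactly 1..%d", n_expected),
           call. = FALSE)
    }
  }
  tab <- tab[order(tab$roi_index), required]
  rownames(tab) <- NULL
  tab
}

#' Write a synthetic cohort to disk
#'
#' Emits one TSV per subject (rows = volumes, columns = ROI labels), one
#' TSV per subject of stored nuisance regressors, a cohort manifest TSV
#' (`subject_id`, `group`, `training_years`, `seed`, `file`) and a JSON
#' copy of the generating spec.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param parcellation Optional parcellation whose abbreviations label the
#'   columns.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, parcellation = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- if (!is.null(parcellation)) {
    paste0(parcellation$abbreviation, "_", parcellation$hemisphere)
  } else NULL
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[i]]
    x <- sub$data
    if (!is.null(labels)) colnames(x) <- labels
    files[i] <- paste0(sub$subject_id, ".tsv")
    utils::write.table(x, file.path(dir, files[i]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(sub$nuisance)) {
      utils::write.table(sub$nuisance,
                         file.path(dir, paste0(sub$subject_id, "_nuisance.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- cohort$manifest
  manifest$file <- files
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(unclass(spec), file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from a manifest and per-subject TSV files
#'
#' Validates dimensional consistency across subjects (and against a
#' parcellation when given) and rejects missing values, reporting the
#' offending subject.
#'
#' @param manifest_path Path to the manifest TSV (`subject_id`, `group`,
#'   `training_years`, `file`; `seed` optional).
#' @param data_dir Directory holding the per-subject TSVs (default: the
#'   manifest's directory).
#' @param tr_seconds Repetition time attached to every subject.
#' @param parcellation Optional parcellation the column count must match.
#' @return A list of class `cohort` with `subjects` and `manifest`.
#' @export
read_cohort <- function(manifest_path, data_dir = dirname(manifest_path),
                        tr_seconds = 2.34, parcellation = NULL) {
  manifest <- utils::read.delim(manifest_path, stringsAsFactors = FALSE,
                                na.strings = c("NA", ""))
  required <- c("subject_id", "group", "training_years", "file")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_group <- which(!manifest$group %in% c("A", "B"))
  if (length(bad_group) > 0) {
    stop(sprintf("subject %s: unknown group label '%s'",
                 manifest$subject_id[bad_group[1]],
                 manifest$group[bad_group[1]]), call. = FALSE)
  }
  n_cols <- NULL
  subjects <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(data_dir, manifest$file[i])
    if (!file.exists(f)) {
      stop(sprintf("subject %s: file not found: %s", manifest$subject_id[i], f),
           call. = FALSE)
    }
    x <- as.matrix(utils::read.delim(f, check.names = FALSE,
                                     na.strings = c("NA", "NaN", "")))
    if (anyNA(x)) {
      stop(sprintf("subject %s: missing values in time series",
                   manifest$subject_id[i]), call. = FALSE)
    }
    if (is.null(n_cols)) n_cols <- ncol(x)
    if (ncol(x) != n_cols) {
      stop(sprintf("subject %s: %d ROI columns; expected %d",
                   manifest$subject_id[i], ncol(x), n_cols), call. = FALSE)
    }
    if (!is.null(parcellation) && ncol(x) != nrow(parcellation)) {
      stop(sprintf("subject %s: %d ROI columns vs %d parcellation rows",
                   manifest$subject_id[i], ncol(x), nrow(parcellation)),
           call. = FALSE)
    }
    nf <- file.path(data_dir, paste0(manifest$subject_id[i], "_nuisance.tsv"))
    nuis <- if (file.exists(nf)) {
      as.matrix(utils::read.delim(nf, check.names = FALSE))
    } else NULL
    subjects[[i]] <- structure(
      list(subject_id = manifest$subject_id[i], group = manifest$group[i],
           data = x, tr_seconds = tr_seconds,
           training_years = manifest$training_years[i], nuisance = nuis),
      class = "subject_ts")
  }
  structure(list(subjects = subjects, manifest = manifest, spec = NULL),
            class = "cohort")
}

fmt3 <- function(d) {
  num <- vapply(d, is.numeric, logical(1)) &
    !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.3f", x))
  d
}

#' Write analysis result tables
#'
#' Emits, under `out_dir`: `auc_global.tsv` (per-subject AUC of each global
#' metric), `group_global.tsv` (mean (SD) per group and permutation p per
#' global metric), `flagged_regions.tsv` (regions significant in at least
#' one nodal metric, with per-metric p and direction), `nodal_tests.tsv`
#' (all region x metric permutation results), `training_correlation.tsv`,
#' and `run_record.json` (full-precision configuration, seed and session
#' versions from which the run can be reproduced). Table floats are
#' rendered at 3 decimals; the JSON keeps full precision.
#'
#' @param results A `netsweep_result` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "netsweep_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  wt <- function(d, name) {
    utils::write.table(fmt3(d), file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(results$global_auc)) wt(results$global_auc, "auc_global.tsv")
  if (!is.null(results$global_tests)) wt(results$global_tests, "group_global.tsv")
  if (!is.null(results$nodal_tests)) wt(results$nodal_tests, "nodal_tests.tsv")
  if (!is.null(results$flagged)) {
    flagged <- results$flagged[results$flagged$flagged, , drop = FALSE]
    wt(flagged, "flagged_regions.tsv")
  }
  if (!is.null(results$training_cor)) {
    wt(results$training_cor, "training_correlation.tsv")
  }
  record <- list(
    spec = if (!is.null(results$spec)) unclass(results$spec) else NULL,
    grid = as.numeric(results$grid),
    n_null = results$config$n_null, swap_factor = results$config$swap_factor,
    n_perm = results$config$n_perm, alpha = results$config$alpha,
    seed = results$config$seed,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("netsweep")))
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
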