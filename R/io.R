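# Tab-separated table IO with schema checks, and the cohort manifest.

trial_schema <- c("run", "t", "chosen", "outcome", "true_high", "payout_high")

check_schema <- function(tbl, required, what) {
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop(what, ": missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(tbl)
}

#' Write a table as tab-separated text
#'
#' Integers and flags round-trip losslessly; doubles are written at 12
#' significant digits.
#'
#' @param tbl A data frame.
#' @param path Output path.
#' @param required Character vector of required columns (schema check).
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(tbl, path, required = character(0)) {
  check_schema(tbl, required, "write_tsv_table")
  out <- as.data.frame(tbl)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- signif(out[[j]], 12)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv_table()]
#'
#' @param path Input path.
#' @param required Character vector of required columns.
#' @return A tibble.
#' @export
read_tsv_table <- function(path, required = character(0)) {
  tbl <- tibble::as_tibble(read.delim(path, sep = "\t", check.names = FALSE))
  check_schema(tbl, required, "read_tsv_table")
  tbl
}

#' Write / read a cohort trial table
#'
#' @param trials Trial tibble (must contain the trial schema columns).
#' @param path File path.
#' @return The path (write) or the tibble (read).
#' @export
write_trials <- function(trials, path) write_tsv_table(trials, path, trial_schema)

#' @rdname write_trials
#' @export
read_trials <- function(path) read_tsv_table(path, trial_schema)

#' Persist a synthetic cohort dataset to a directory
#'
#' Writes the trial table, belief series and univariate signals as TSV, every
#' pattern matrix as a TSV matrix, pupil traces and feedback times as TSV,
#' and a JSON manifest recording the master seed, configs, software version,
#' and the full file inventory with shapes and MD5 hashes. The manifest is
#' written last via an atomic rename, so a partial write never leaves a
#' valid-looking manifest behind.
#'
#' @param dataset A `cohort_dataset` from [generate_cohort_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inv <- list()
  add <- function(name, path, shape) {
    inv[[length(inv) + 1]] <<- list(
      name = name, file = basename(path), shape = shape,
      md5 = unname(tools::md5sum(path))
    )
  }
  p <- file.path(dir, "trials.tsv")
  write_trials(dataset$trials, p); add("trials", p, dim(dataset$trials))
  p <- file.path(dir, "beliefs.tsv")
  write_tsv_table(dataset$beliefs, p); add("beliefs", p, dim(dataset$beliefs))
  p <- file.path(dir, "univariate.tsv")
  write_tsv_table(dataset$univariate, p); add("univariate", p, dim(dataset$univariate))
  for (s in names(dataset$patterns)) {
    for (reg in names(dataset$patterns[[s]])) {
      p <- file.path(dir, sprintf("patterns_sub%s_%s.tsv", s, reg))
      act <- dataset$patterns[[s]][[reg]]$activity
      write.table(signif(act, 12), p, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
      add(sprintf("patterns/sub%s/%s", s, reg), p, dim(act))
    }
  }
  for (s in names(dataset$pupil)) {
    p <- file.path(dir, sprintf("pupil_trace_sub%s.tsv", s))
    write_tsv_table(dataset$pupil[[s]]$trace, p,
                    c("run", "time_ms", "value", "is_missing"))
    add(sprintf("pupil/sub%s/trace", s), p, dim(dataset$pupil[[s]]$trace))
    p <- file.path(dir, sprintf("pupil_feedback_sub%s.tsv", s))
    write_tsv_table(dataset$pupil[[s]]$feedback_ms, p, c("run", "t", "feedback_ms"))
    add(sprintf("pupil/sub%s/feedback", s), p, dim(dataset$pupil[[s]]$feedback_ms))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("beliefstate")),
    master_seed = dataset$configs$master_seed,
    n_subjects = length(unique(dataset$trials$subject)),
    configs = lapply(
      dataset$configs[c("task", "observer", "state", "action", "pupil")],
      function(cfg) lapply(unclass(cfg), function(x) if (is.list(x)) x else unclass(x))
    ),
    inventory = inv
  )
  tmp <- tempfile(tmpdir = dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, file.path(dir, "manifest.json"))
  invisible(file.path(dir, "manifest.json"))
}

#' Read and verify a cohort manifest
#'
#' Checks that every file in the inventory exists and that its MD5 hash
#' matches the manifest.
#'
#' @param dir Cohort directory containing `manifest.json`.
#' @return The manifest as a list.
#' @export
read_manifest <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("read_manifest: no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  for (item in manifest$inventory) {
    f <- file.path(dir, item$file)
    if (!file.exists(f)) stop("read_manifest: missing file ", item$file, call. = FALSE)
    if (!identical(unname(tools::md5sum(f)), item$md5)) {
      stop("read_manifest: hash mismatch for ", item$file, call. = FALSE)
    }
  }
  manifest
}
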