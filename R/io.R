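#' Read a participant table (intake or response panel) from CSV
#'
#' Expects RFC 4180 CSV with a header row and the participant id in the
#' first column. The table must be complete-case: any missing cell is
#' rejected with a listing of the offending rows and columns (participants
#' with missing data are excluded upstream, never imputed). Duplicate ids
#' and non-numeric data cells are rejected too. A `wave` column (character)
#' and, for intake tables, an `energy_kj` column are recognised as metadata.
#'
#' @param path Path to a CSV file.
#' @param kind `"intake"` or `"response"`; intake tables must be nonnegative
#'   and have at least 2 food columns.
#' @return A tibble with `participant_id` first, a `wave` column when
#'   present, then numeric variable columns.
#' @export
read_table <- function(path, kind = c("intake", "response")) {
  kind <- match.arg(kind)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("table needs an id column plus at least one variable")
  names(raw)[1] <- "participant_id"
  ids <- raw$participant_id
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate participant ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  vars <- setdiff(names(raw), c("participant_id", "wave"))
  out <- raw
  for (v in vars) {
    val <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(is.na(val))
    if (length(bad) > 0) {
      missing_cells <- paste0("row ", bad, " (id ", ids[bad], "), column '", v, "'")
      abort(paste0(length(bad), " missing or non-numeric cell(s): ",
                   paste(head(missing_cells, 10), collapse = "; ")))
    }
    out[[v]] <- val
  }
  if (kind == "intake") {
    foods <- setdiff(vars, ENERGY_COL)
    if (length(foods) < 2) abort("intake table needs at least 2 food columns")
    neg <- foods[vapply(foods, function(f) any(out[[f]] < 0), logical(1))]
    if (length(neg) > 0) {
      abort(paste0("negative intakes in column(s): ", paste(neg, collapse = ", ")))
    }
    if (ENERGY_COL %in% vars && any(out[[ENERGY_COL]] <= 0)) {
      abort("energy_kj must be positive")
    }
  }
  out
}

#' Write a participant table to CSV
#'
#' Writes in the same RFC 4180 dialect [read_table()] reads, so that a
#' read/write round trip is lossless on the data region.
#'
#' @param data A participant table.
#' @param path Output path.
#' @return The input, invisibly.
#' @export
write_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Pipeline configuration
#'
#' Collects every threshold and size the two-wave analysis pipeline uses:
#' the backwards-elimination p-value threshold, the cross-wave retention
#' rule, the Monte-Carlo cross-validation geometry, the Van der Voet test
#' settings, the high-weight threshold and the energy-adjustment switch.
#'
#' @param alpha_backwards p-value threshold for backwards elimination.
#' @param min_responses_retained Responses a food must survive (>= 3 reads
#'   "more than two").
#' @param wave_rule `"either"` or `"both"` waves for the retention rule.
#' @param cv_n_splits Number of random cross-validation test sets.
#' @param cv_test_fraction Held-out fraction per split.
#' @param vandervoet_alpha Significance level for pattern-count selection.
#' @param n_randomizations Sign-flip draws per Van der Voet test.
#' @param k_max Cap on candidate pattern counts.
#' @param weight_highlight_threshold |weight| threshold for flags/labels.
#' @param energy_adjust Apply the energy-residual method to foods first.
#' @param confirmatory_standardize Standardization reference for
#'   confirmatory scoring (`"data"` or `"training"`).
#' @param seed Integer seed driving all pipeline randomness.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_backwards = 0.05,
                            min_responses_retained = 3,
                            wave_rule = "either",
                            cv_n_splits = 1000,
                            cv_test_fraction = 0.1,
                            vandervoet_alpha = 0.10,
                            n_randomizations = 2000,
                            k_max = 6,
                            weight_highlight_threshold = 0.10,
                            energy_adjust = FALSE,
                            confirmatory_standardize = "data",
                            seed = NULL) {
  stopifnot(alpha_backwards > 0, alpha_backwards < 1,
            cv_test_fraction > 0, cv_test_fraction < 1,
            vandervoet_alpha > 0, vandervoet_alpha < 1,
            cv_n_splits >= 1, n_randomizations >= 1,
            min_responses_retained >= 1, k_max >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat YAML keys matching the arguments of [pipeline_config()]; unknown
#' keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}
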