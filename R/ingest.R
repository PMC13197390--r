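# Reading, validating, aggregating and reshaping AOI fixation-duration
# exports. The canonical on-disk dialects:
#   long: UTF-8 TSV, header  participant<TAB>task<TAB>aoi<TAB>tdof_ms
#   wide: CSV, header        participant,task,<AOI1>,...,<AOID>
# In memory a fixation table is a long tibble with exactly those four
# columns; dwell times are total durations of fixations (TDoF) in ms.

#' Read an AOI fixation-duration export
#'
#' Parses a long TSV (`participant`, `task`, `aoi`, `tdof_ms`) or a wide CSV
#' (`participant`, `task`, one column per AOI) into a long fixation table.
#' Unknown columns are dropped with a warning. Any (participant, task) pair
#' that is present but lacks a record for some AOI is completed with an
#' explicit zero, so that unvisited AOIs are observable and can be routed
#' through the zero policy downstream.
#'
#' @param path File to read.
#' @param dialect `"long"` (TSV) or `"wide"` (CSV).
#' @param aoi_set Optional character vector fixing the AOI order; defaults to
#'   first-appearance order (long) or column order (wide).
#' @param quiet Suppress the parsing summary message.
#' @return A long tibble with columns `participant`, `task`, `aoi`
#'   (factor with the AOI order), `tdof_ms`. Completed cells are flagged in
#'   the logical column `imputed_zero`.
#' @export
read_fixation_table <- function(path, dialect = c("long", "wide"),
                                aoi_set = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "long") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    needed <- c("participant", "task", "aoi", "tdof_ms")
    missing <- setdiff(needed, names(raw))
    if (length(missing) > 0L) {
      abort(paste0(
        "Long dialect requires columns ", paste(needed, collapse = ", "),
        "; missing: ", paste(missing, collapse = ", ")
      ))
    }
    extra <- setdiff(names(raw), needed)
    if (length(extra) > 0L) {
      warn(paste0("Ignoring unknown column(s): ", paste(extra, collapse = ", ")))
      raw <- raw[needed]
    }
    long <- raw
  } else {
    raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    needed <- c("participant", "task")
    missing <- setdiff(needed, names(raw))
    if (length(missing) > 0L) {
      abort(paste0("Wide dialect requires columns ", paste(needed, collapse = ", ")))
    }
    aois <- setdiff(names(raw), needed)
    if (length(aois) < 2L) abort("Wide dialect needs at least 2 AOI columns.")
    long <- tidyr::pivot_longer(raw, dplyr::all_of(aois),
      names_to = "aoi", values_to = "tdof_ms"
    )
  }
  long$tdof_ms <- as.numeric(long$tdof_ms)
  bad_num <- which(is.na(long$tdof_ms))
  if (length(bad_num) > 0L) {
    abort(paste0(
      "Unparseable or missing dwell time in row(s): ",
      paste(head(bad_num, 10), collapse = ", ")
    ))
  }
  neg <- which(long$tdof_ms < 0)
  if (length(neg) > 0L) {
    abort(paste0(
      "Negative dwell time(s) in row(s): ", paste(head(neg, 10), collapse = ", ")
    ))
  }
  dup <- duplicated(long[c("participant", "task", "aoi")])
  if (any(dup)) {
    abort(paste0(
      "Duplicate (participant, task, aoi) record(s) in row(s): ",
      paste(head(which(dup), 10), collapse = ", ")
    ))
  }
  aoi_set <- aoi_set %||% unique(as.character(long$aoi))
  unknown <- setdiff(unique(as.character(long$aoi)), aoi_set)
  if (length(unknown) > 0L) {
    abort(paste0("AOI(s) outside `aoi_set`: ", paste(unknown, collapse = ", ")))
  }
  out <- as_fixation_table(long, aoi_set = aoi_set)
  if (!quiet) {
    inform(sprintf(
      "Read %d records: %d participants x %d tasks x %d AOIs (%d cell(s) completed as zero).",
      nrow(out), dplyr::n_distinct(out$participant),
      dplyr::n_distinct(out$task), length(aoi_set), sum(out$imputed_zero)
    ))
  }
  out
}

#' Coerce a long data frame into a complete fixation table
#'
#' Ensures one record per (participant, task, AOI) for every (participant,
#' task) pair present, materialising missing AOI cells as zeros flagged in
#' `imputed_zero`.
#'
#' @param data Long data frame with `participant`, `task`, `aoi`, `tdof_ms`.
#' @param aoi_set Optional AOI ordering.
#' @return A long tibble sorted by participant, task, AOI.
#' @export
as_fixation_table <- function(data, aoi_set = NULL) {
  data <- tibble::as_tibble(data)
  aoi_set <- aoi_set %||% unique(as.character(data$aoi))
  data$aoi <- factor(as.character(data$aoi), levels = aoi_set)
  observed <- data
  observed$imputed_zero <- FALSE
  completed <- tidyr::complete(
    observed,
    tidyr::nesting(participant, task),
    aoi = factor(aoi_set, levels = aoi_set),
    fill = list(tdof_ms = 0, imputed_zero = TRUE)
  )
  dplyr::arrange(completed, .data$participant, .data$task, .data$aoi)[
    , c("participant", "task", "aoi", "tdof_ms", "imputed_zero")
  ]
}

#' Write a fixation table in a canonical dialect
#'
#' @param data Long fixation table.
#' @param path Output file.
#' @param dialect `"long"` TSV or `"wide"` CSV.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(data, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    readr::write_tsv(data[c("participant", "task", "aoi", "tdof_ms")], path,
      progress = FALSE
    )
  } else {
    wide <- tidyr::pivot_wider(
      data[c("participant", "task", "aoi", "tdof_ms")],
      names_from = "aoi", values_from = "tdof_ms"
    )
    readr::write_csv(wide, path, progress = FALSE)
  }
  invisible(path)
}

#' Aggregate AOIs into coarser groups
#'
#' Sums dwell times within each (participant, task) over groups of AOIs —
#' for example collapsing a seven-AOI scheme into Visitor / Persons /
#' Background. Aggregation conserves per-row totals exactly, and is the
#' preferred remedy for sparsely visited AOIs that would otherwise need zero
#' imputation.
#'
#' @param data Long fixation table.
#' @param mapping Named character vector `c(aoi = group, ...)` covering every
#'   AOI present; group order follows first appearance in `mapping`.
#' @return A long fixation table over the group labels.
#' @export
aggregate_aois <- function(data, mapping) {
  aois <- unique(as.character(data$aoi))
  unmapped <- setdiff(aois, names(mapping))
  if (length(unmapped) > 0L) {
    abort(paste0("Unmapped AOI(s): ", paste(unmapped, collapse = ", ")))
  }
  group_order <- unique(unname(mapping))
  out <- data |>
    dplyr::mutate(group = factor(unname(mapping[as.character(.data$aoi)]),
      levels = group_order
    )) |>
    dplyr::group_by(.data$participant, .data$task, .data$group) |>
    dplyr::summarise(tdof_ms = sum(.data$tdof_ms), .groups = "drop") |>
    dplyr::rename(aoi = "group")
  as_fixation_table(out, aoi_set = group_order)
}

#' Reshape a fixation table into a wide composition table
#'
#' Pivots a long fixation table to one row per (participant, task) with one
#' column per AOI. Rows whose total dwell time is zero carry no relative
#' information and are dropped with a warning; remaining zeros are handled by
#' the requested policy so the result is strictly positive and ready for the
#' log-ratio machinery.
#'
#' @param data Long fixation table.
#' @param tasks Optional task filter (vector of task ids to keep).
#' @param zero_policy `"replace"` (impute via [replace_zeros()]) or `"none"`
#'   (fail if zeros remain).
#' @param fraction Column-minimum fraction for the replacement policy.
#' @param quiet Suppress replacement messages.
#' @return Wide tibble: `participant`, `task`, then one positive numeric
#'   column per AOI.
#' @export
to_composition_matrix <- function(data, tasks = NULL,
                                  zero_policy = c("replace", "none"),
                                  fraction = 0.65, quiet = FALSE) {
  zero_policy <- match.arg(zero_policy)
  if (!is.null(tasks)) {
    data <- dplyr::filter(data, .data$task %in% tasks)
    if (nrow(data) == 0L) abort("No records left after the task filter.")
  }
  wide <- tidyr::pivot_wider(
    data[c("participant", "task", "aoi", "tdof_ms")],
    names_from = "aoi", values_from = "tdof_ms"
  )
  parts <- setdiff(names(wide), c("participant", "task"))
  totals <- rowSums(wide[parts])
  if (any(totals == 0)) {
    warn(paste0(
      "Dropping ", sum(totals == 0),
      " row(s) with zero total dwell time (no relative information)."
    ))
    wide <- wide[totals > 0, , drop = FALSE]
  }
  if (zero_policy == "replace") {
    if (any(as.matrix(wide[parts]) == 0)) {
      wide <- replace_zeros(wide, parts, fraction = fraction, quiet = quiet)
    }
  } else if (any(as.matrix(wide[parts]) == 0)) {
    abort("Zeros remain and `zero_policy = \"none\"`; impute or aggregate first.")
  }
  wide
}

#' Validate the participant x task design of a fixation table
#'
#' Reports (without failing) missing participant-task cells relative to the
#' full crossed design, zero counts per AOI, and per-task row counts —
#' including AOIs that are entirely zero within some task, which are
#' candidates for merging.
#'
#' @param data Long fixation table.
#' @return A list of class `design_report` with tibbles `missing_cells`,
#'   `zero_counts`, `task_rows`, and `merge_candidates`.
#' @export
validate_design <- function(data) {
  participants <- unique(data$participant)
  tasks <- unique(data$task)
  grid <- tidyr::expand_grid(participant = participants, task = tasks)
  present <- dplyr::distinct(data, .data$participant, .data$task)
  missing_cells <- dplyr::anti_join(grid, present, by = c("participant", "task"))
  zero_counts <- data |>
    dplyr::group_by(.data$aoi) |>
    dplyr::summarise(n_zero = sum(.data$tdof_ms == 0), .groups = "drop")
  task_rows <- present |>
    dplyr::count(.data$task, name = "n_participants")
  merge_candidates <- data |>
    dplyr::group_by(.data$task, .data$aoi) |>
    dplyr::summarise(all_zero = all(.data$tdof_ms == 0), .groups = "drop") |>
    dplyr::filter(.data$all_zero) |>
    dplyr::select("task", "aoi")
  structure(
    list(
      missing_cells = missing_cells,
      zero_counts = zero_counts,
      task_rows = task_rows,
      merge_candidates = merge_candidates
    ),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat("Design report\n")
  cat("  missing participant-task cells:", nrow(x$missing_cells), "\n")
  cat("  zero cells per AOI:\n")
  zc <- x$zero_counts
  for (i in seq_len(nrow(zc))) {
    cat("    ", as.character(zc$aoi[i]), ": ", zc$n_zero[i], "\n", sep = "")
  }
  if (nrow(x$merge_candidates) > 0) {
    cat("  all-zero AOI-within-task (merge candidates):\n")
    print(x$merge_candidates)
  }
  invisible(x)
}
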