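# Task-level descriptive summaries, in two parallel tracks: compositional
# (geometric means, variation matrices) and classical (arithmetic means,
# Pearson correlations on raw ms).

#' Summarise each task on the compositional and classical tracks
#'
#' For every task with at least `min_n` rows, computes the compositional mean
#' (closed to percentages), the variation matrix with its total variance, the
#' arithmetic mean dwell times in ms, and the Pearson correlation matrix of
#' raw dwell times. Undersized tasks are skipped with a warning.
#'
#' @param data Wide composition table (see [to_composition_matrix()]).
#' @param parts Optional part column names.
#' @param min_n Minimum rows per task (default 2, the variation-matrix
#'   minimum).
#' @param divisor Variance divisor passed to [variation_matrix()].
#' @return A tibble with one row per task: `task`, `n`, `totvar`, and
#'   list-columns `mean_composition` (named vector, sums to 100),
#'   `arithmetic_means` (named vector, ms), `variation`
#'   ([variation_matrix] object), `correlation` (D x D matrix).
#' @export
summarize_tasks <- function(data, parts = NULL, min_n = 2L,
                            divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  parts <- part_cols(data, parts)
  if (!"task" %in% names(data)) abort("`data` must have a `task` column.")
  tasks <- sort(unique(data$task))
  rows <- purrr::map(tasks, function(tk) {
    sub <- data[data$task == tk, , drop = FALSE]
    if (nrow(sub) < min_n) {
      warn(paste0("Task ", tk, " has fewer than ", min_n, " rows; skipped."))
      return(NULL)
    }
    vm <- variation_matrix(sub, parts, divisor)
    tibble::tibble(
      task = tk,
      n = nrow(sub),
      totvar = vm$totvar,
      mean_composition = list(compositional_mean(sub, parts, kappa = 100)),
      arithmetic_means = list(colMeans(as.matrix(sub[parts]))),
      variation = list(vm),
      correlation = list(stats::cor(as.matrix(sub[parts])))
    )
  })
  dplyr::bind_rows(rows)
}

#' Tidy table of task means, both tracks
#'
#' @param summaries Output of [summarize_tasks()].
#' @return A long tibble: `task`, `aoi`, `mean_pct` (compositional mean,
#'   percent), `mean_ms` (arithmetic mean, ms).
#' @export
task_mean_table <- function(summaries) {
  purrr::pmap_dfr(
    summaries[c("task", "mean_composition", "arithmetic_means")],
    function(task, mean_composition, arithmetic_means) {
      tibble::tibble(
        task = task,
        aoi = names(mean_composition),
        mean_pct = unname(mean_composition),
        mean_ms = unname(arithmetic_means[names(mean_composition)])
      )
    }
  )
}

#' Planar (barycentric) coordinates for three-part compositions
#'
#' Places each closed three-part composition `(a, b, c)` inside the triangle
#' with vertices A = (0, 0), B = (1, 0), C = (1/2, sqrt(3)/2) at the affine
#' combination `a*A + b*B + c*C`. The uniform composition maps to the
#' centroid; compositions dominated by one part approach that part's vertex.
#' Coordinates depend only on the closed composition, so they are invariant
#' to rescaling of the raw dwell times.
#'
#' @param data Wide composition table with exactly three part columns.
#' @param parts Optional part column names (length 3).
#' @return `data` as a tibble with planar columns `.x` and `.y` appended.
#' @seealso [plot_ternary()]
#' @export
ternary_coordinates <- function(data, parts = NULL) {
  parts <- part_cols(data, parts)
  if (length(parts) != 3L) {
    abort("Ternary coordinates require exactly 3 parts; aggregate AOIs first.")
  }
  m <- comp_values(data, parts)
  p <- m / rowSums(m)
  out <- tibble::as_tibble(data)
  out$.x <- unname(p[, 2] + 0.5 * p[, 3])
  out$.y <- unname(sqrt(3) / 2 * p[, 3])
  out
}

#' Log-ratio contrast of task means against the pooled mean
#'
#' For each task and AOI, computes `ln(g_task / g_all)` where `g_task` and
#' `g_all` are the task-specific and pooled compositional means, both closed
#' to unit sum before the ratio. Values near zero indicate that the task's
#' relative allocation to that AOI agrees with the pooled mean; positive
#' values mark AOIs relatively over-attended in that task. Closing both means
#' first makes the contrast invariant to the closure constant of the raw
#' data.
#'
#' @param data Wide composition table with a `task` column.
#' @param parts Optional part column names.
#' @return A tibble: `task`, `aoi`, `contrast`.
#' @export
mean_contrast_logratio <- function(data, parts = NULL) {
  parts <- part_cols(data, parts)
  if (!"task" %in% names(data)) abort("`data` must have a `task` column.")
  overall <- compositional_mean(data, parts, kappa = 1)
  purrr::map_dfr(sort(unique(data$task)), function(tk) {
    sub <- data[data$task == tk, , drop = FALSE]
    tm <- compositional_mean(sub, parts, kappa = 1)
    tibble::tibble(
      task = tk,
      aoi = parts,
      contrast = log(unname(tm) / unname(overall[names(tm)]))
    )
  })
}
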