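# Seeded generator of synthetic AOI dwell-time experiments with the
# statistical structure the compositional analysis assumes: logistic-normal
# compositions (Gaussian noise in ilr space mapped back to the simplex),
# participant random effects, task-specific mean compositions, and lognormal
# per-row total viewing times. The compositional signal and the total-time
# scale are generated independently, so the two analysis tracks can be
# pulled apart deliberately.

#' The study AOI labels
#'
#' Canonical ordering of the seven areas of interest used throughout the
#' package's presets.
#' @return Character vector of length 7.
#' @export
study_aois <- function() {
  c("Background", "Furniture", "Kids", "Maid", "Man", "Mother", "Wife")
}

#' Pooled mean composition preset
#'
#' The across-task mean allocation of viewing time over the seven AOIs, in
#' percent, used as the default centre of the null generator.
#' @return Named numeric vector summing to 100.
#' @export
pooled_mean_composition <- function() {
  setNames(
    c(12.52, 2.33, 19.21, 16.19, 20.22, 17.71, 11.82),
    study_aois()
  )
}

#' Task-mean composition preset with Yarbus-like structure
#'
#' An illustrative 7-task scenario qualitatively mirroring the classic
#' task-dependence pattern: free viewing (task 1) spreads attention with a
#' large Background share; furniture is almost ignored in the person-focused
#' tasks 3, 5 and 7; task 4 concentrates on the children; task 7 elevates
#' the returning man above half of the viewing time. The values are
#' illustrative round numbers, not estimates fitted to any dataset.
#'
#' @return A 7 x 7 matrix (tasks x AOIs), each row summing to 100.
#' @export
task_means_yarbus <- function() {
  m <- rbind(
    c(33, 14.0, 12, 9, 12, 11, 9.0),
    c(22, 20.0, 13, 9, 13, 12, 11.0),
    c(6, 0.8, 24, 16, 19, 18, 16.2),
    c(14, 15.0, 30, 8, 12, 11, 10.0),
    c(8, 1.0, 22, 18, 18, 18, 15.0),
    c(24, 18.0, 14, 10, 12, 12, 10.0),
    c(7, 1.0, 9, 7, 52, 14, 10.0)
  )
  dimnames(m) <- list(paste0("task", 1:7), study_aois())
  m
}

validate_task_means <- function(task_means) {
  if (!is.matrix(task_means) || ncol(task_means) < 2L) {
    abort("`task_means` must be a K x D matrix (tasks in rows, AOIs in columns).")
  }
  if (any(!is.finite(task_means) | task_means <= 0)) {
    abort("Task mean compositions must be strictly positive.")
  }
  if (is.null(colnames(task_means))) {
    colnames(task_means) <- paste0("AOI", seq_len(ncol(task_means)))
  }
  task_means
}

#' Simulate a synthetic AOI dwell-time experiment
#'
#' Generates one row per participant x task. The composition of row (i, k)
#' is the task mean perturbed by a participant effect and residual noise:
#' in ilr space, `z_ik = ilr(mu_k) + p_i + e_ik` with
#' `p_i ~ N(0, sigma_p^2 I)` shared across a participant's tasks and
#' `e_ik ~ N(0, sigma_e^2 I)` independent per row. The resulting
#' logistic-normal composition is scaled to a lognormal total viewing time
#' `T_ik` (ms), which carries no compositional information. Optionally a
#' fraction of cells is then zeroed to emulate unvisited AOIs. Identical
#' seeds give byte-identical tables.
#'
#' @param n_participants Number of participants (default 144).
#' @param task_means K x D matrix of task mean compositions (rows need not be
#'   closed; default [task_means_yarbus()]).
#' @param sigma_p Participant random-effect scale in ilr space (default 0.3).
#' @param sigma_e Residual scale in ilr space (default 0.5).
#' @param total_meanlog,total_sdlog Lognormal parameters of the per-row total
#'   viewing time in ms; scalars or per-task vectors (defaults
#'   `log(15000)` and 0.5).
#' @param zero_rate Fraction of cells zeroed after generation, in [0, 0.5].
#' @param seed Integer seed (required).
#' @return A long fixation table (see [as_fixation_table()]).
#' @export
simulate_experiment <- function(n_participants = 144,
                                task_means = task_means_yarbus(),
                                sigma_p = 0.3, sigma_e = 0.5,
                                total_meanlog = log(15000),
                                total_sdlog = 0.5,
                                zero_rate = 0, seed) {
  if (missing(seed) || !is.numeric(seed)) abort("A numeric `seed` is required.")
  task_means <- validate_task_means(task_means)
  if (sigma_p < 0 || sigma_e < 0) abort("Noise scales must be nonnegative.")
  if (zero_rate < 0 || zero_rate > 0.5) abort("`zero_rate` must lie in [0, 0.5].")
  K <- nrow(task_means)
  D <- ncol(task_means)
  aois <- colnames(task_means)
  total_meanlog <- rep_len(total_meanlog, K)
  total_sdlog <- rep_len(total_sdlog, K)
  Vb <- pivot_basis(D)
  mu_z <- t(apply(task_means, 1, function(mu) ilr_pivot(close_composition(mu))))
  wide <- withr::with_seed(as.integer(seed), {
    pe <- matrix(rnorm(n_participants * (D - 1), sd = sigma_p),
      nrow = n_participants
    )
    rows <- purrr::map(seq_len(K), function(k) {
      e <- matrix(rnorm(n_participants * (D - 1), sd = sigma_e),
        nrow = n_participants
      )
      z <- sweep(pe + e, 2, mu_z[k, ], "+")
      y <- z %*% t(Vb)
      x <- exp(y)
      props <- x / rowSums(x)
      totals <- rlnorm(n_participants, total_meanlog[k], total_sdlog[k])
      m <- props * totals
      colnames(m) <- aois
      dplyr::bind_cols(
        tibble::tibble(
          participant = sprintf("P%03d", seq_len(n_participants)),
          task = k
        ),
        tibble::as_tibble(m)
      )
    })
    dplyr::bind_rows(rows)
  })
  long <- tidyr::pivot_longer(wide, dplyr::all_of(aois),
    names_to = "aoi", values_to = "tdof_ms"
  )
  out <- as_fixation_table(long, aoi_set = aois)
  if (zero_rate > 0) {
    out <- inject_zeros(out, rate = zero_rate, seed = as.integer(seed) + 1L)
  }
  out
}

#' Simulate under the null of identical task means
#'
#' As [simulate_experiment()] but with every task sharing one mean
#' composition, so any apparent task effect is noise. Used for type-I error
#' and chance-level classification checks.
#'
#' @param n_participants Number of participants.
#' @param n_tasks Number of tasks.
#' @param mean Common mean composition (default [pooled_mean_composition()]).
#' @inheritParams simulate_experiment
#' @return A long fixation table.
#' @export
simulate_null <- function(n_participants = 144, n_tasks = 7,
                          mean = pooled_mean_composition(),
                          sigma_p = 0.3, sigma_e = 0.5,
                          total_meanlog = log(15000), total_sdlog = 0.5,
                          zero_rate = 0, seed) {
  task_means <- matrix(rep(mean, each = n_tasks),
    nrow = n_tasks,
    dimnames = list(NULL, names(mean) %||% paste0("AOI", seq_along(mean)))
  )
  simulate_experiment(
    n_participants = n_participants, task_means = task_means,
    sigma_p = sigma_p, sigma_e = sigma_e,
    total_meanlog = total_meanlog, total_sdlog = total_sdlog,
    zero_rate = zero_rate, seed = seed
  )
}

#' Zero out random cells of a fixation table
#'
#' Emulates unvisited AOIs: each cell is independently zeroed with
#' probability `rate`, except that a row (participant x task) is never
#' zeroed completely — the cell with the longest dwell time is kept when the
#' draw would empty a row. Deterministic given the seed.
#'
#' @param data Long fixation table.
#' @param rate Zeroing probability per cell, in [0, 0.5].
#' @param seed Integer seed.
#' @return The fixation table with zeros injected.
#' @export
inject_zeros <- function(data, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate > 0.5) {
    abort("`rate` must lie in [0, 0.5].")
  }
  if (rate == 0) {
    return(data)
  }
  if (missing(seed) || !is.numeric(seed)) abort("A numeric `seed` is required.")
  n <- nrow(data)
  hit <- withr::with_seed(as.integer(seed), runif(n) < rate)
  df <- tibble::as_tibble(data)
  df$.hit <- hit
  df <- df |>
    dplyr::group_by(.data$participant, .data$task) |>
    dplyr::mutate(.hit = .data$.hit &
      !(all(.data$.hit) & dplyr::row_number(-.data$tdof_ms) == 1L)) |>
    dplyr::ungroup()
  df$tdof_ms[df$.hit] <- 0
  df$.hit <- NULL
  df
}
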