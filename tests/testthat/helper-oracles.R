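# Shared fixtures and independent brute-force oracles used across tests.

# Two-observer dwell-time fixture (Visitor / Persons / Background, ms).
p74 <- c(Visitor = 8323, Persons = 5353, Background = 4319)
p101 <- c(Visitor = 2187, Persons = 1377.3, Background = 1036)

# Random strictly positive composition, reproducibly.
rand_comp <- function(D, seed) {
  withr::with_seed(seed, exp(rnorm(D)))
}

# Random composition table with id columns, one task.
rand_comp_table <- function(n, D, seed, parts = paste0("A", seq_len(D))) {
  m <- withr::with_seed(seed, matrix(exp(rnorm(n * D)), nrow = n))
  colnames(m) <- parts
  dplyr::bind_cols(
    tibble::tibble(participant = sprintf("P%02d", seq_len(n)), task = 1L),
    tibble::as_tibble(m)
  )
}

# Brute-force variation matrix: explicit double loop over log-ratio columns.
oracle_variation <- function(m, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  D <- ncol(m)
  n <- nrow(m)
  t_mat <- matrix(0, D, D)
  for (j in seq_len(D)) {
    for (k in seq_len(D)) {
      lr <- log(m[, j] / m[, k])
      v <- sum((lr - mean(lr))^2) / (n - 1)
      if (divisor == "ml") v <- v * (n - 1) / n
      t_mat[j, k] <- v
    }
  }
  t_mat
}

# Brute-force complete-linkage agglomeration: at each step scan every pair
# of current clusters for the smallest farthest-neighbour distance. Returns
# the merge heights in order.
oracle_complete_linkage <- function(d_full) {
  cl <- as.list(seq_len(nrow(d_full)))
  heights <- numeric(0)
  while (length(cl) > 1L) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in seq_along(cl)) {
      for (j in seq_along(cl)) {
        if (i < j) {
          h <- max(d_full[cl[[i]], cl[[j]]])
          if (h < best) {
            best <- h
            bi <- i
            bj <- j
          }
        }
      }
    }
    heights <- c(heights, best)
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl[[bj]] <- NULL
  }
  heights
}

# Write a small long-format TSV fixture and return its path.
write_fixture_tsv <- function(df, dir = tempdir()) {
  path <- tempfile("fixation", tmpdir = dir, fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}
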