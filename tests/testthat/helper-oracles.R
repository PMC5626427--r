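# Independent oracles and fixture builders used across tests.

# Brute-force Spearman: explicit Pearson correlation of mid-ranks, computed
# with elementwise sums (no cor()), plus the t-approximation p-value.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(list(rho = NA_real_, p = NA_real_))
  rho <- num / den
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE))
}

# Exhaustive-scan event oracle: flags every visit (from the 3rd) below
# baseline - k * sd * sqrt(1.5) and searches all indices for the earliest one
# heading a run of >= confirm + 1 consecutive flags.
oracle_event <- function(values, fluct_sd, k = 2, confirm = 1L,
                         confirm_at_end = FALSE) {
  thr <- mean(values[1:2]) - k * fluct_sd * sqrt(1.5)
  n <- length(values)
  flag <- values < thr
  flag[1:2] <- FALSE
  for (i in seq_len(n)) {
    if (i < 3 || !flag[i]) next
    need <- i + confirm
    if (need <= n && all(flag[i:need])) return(i)
    if (confirm_at_end) {
      # run truncated by series end
      if (all(flag[i:n])) return(i)
    }
  }
  NA_integer_
}

# Minimal hand-built one-eye cohort CSV (5 visits, mRNFL grids + cpRNFL,
# no VF). `grid_fn(visit)` returns a 10x10 matrix in *native* orientation.
write_tiny_cohort <- function(path, laterality = "OD", quality = rep(90, 5),
                              grid_fn = function(v) matrix(30, 10, 10)) {
  dates <- c(0, 200, 400, 600, 800)
  pts <- expand.grid(col = 1:10, row = 1:10)[, c("row", "col")]
  rows <- list()
  for (v in seq_along(dates)) {
    g <- grid_fn(v)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = "p1", eye_id = "e1", laterality = laterality,
      date = dates[v], block = "macular", quality = quality[v],
      layer = "mRNFL", clock_hour = NA_integer_,
      row = pts$row, col = pts$col,
      thickness = g[cbind(pts$row, pts$col)],
      sensitivity = NA_real_, total_deviation = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = "p1", eye_id = "e1", laterality = laterality,
      date = dates[v], block = "cprnfl", quality = NA_real_,
      layer = NA_character_, clock_hour = 1:12,
      row = NA_integer_, col = NA_integer_, thickness = 100,
      sensitivity = NA_real_, total_deviation = NA_real_)
  }
  readr::write_csv(do.call(rbind, rows), path, progress = FALSE)
  path
}

# A fast small simulated cohort shared by several tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(n_eyes = 40), seed = 101)
    }
    cache
  }
})
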