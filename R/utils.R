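# Internal numeric helpers shared across the pipeline.

# Trapezoidal rule on an irregular grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Centered moving average with shrinking windows at the edges, so the
# smoothed trace has the same length and no NA padding.
smooth_ma <- function(y, k = 5L) {
  n <- length(y)
  if (n < k || k < 2L) return(y)
  h <- (k - 1L) %/% 2L
  s <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  for (i in seq_len(h)) {
    s[i] <- mean(y[1:(i + h)])
    s[n - i + 1L] <- mean(y[(n - i + 1L - h):n])
  }
  s
}

# Sample CV in percent; NA mean or zero mean yields NA.
cv_pct <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) return(NA_real_)
  stats::sd(x) / m * 100
}

# Low-overhead tibble construction for hot paths (peak records, simulated
# traces); skips tibble()'s quosure machinery.
fast_tibble <- function(lst) {
  tibble::new_tibble(lst, nrow = length(lst[[1]]))
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
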