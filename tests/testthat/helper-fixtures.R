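# Shared fixtures and independent oracles used across test files.

# Small geometric concentration ladder with known integer-friendly values.
make_ref <- function(n = 10, base = 2) {
  ercc_reference(
    control_id = sprintf("CTRL-%02d", seq_len(n)),
    concentration = base^(seq_len(n) - 1),
    length = rep(1000L, n)
  )
}

# Counts exactly proportional to concentration (noise-free dose-response).
proportional_counts <- function(ref, k = 100, total_reads = NULL) {
  per <- stats::setNames(k * ref$concentration, ref$control_id)
  ercc_counts(per, total_reads = total_reads %||% (2 * sum(per)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form simple linear regression on (x, y): slope, intercept, R^2.
# Independent of stats::lm on purpose.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- syy - sy^2 / n
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

# Pearson correlation computed from scratch (for the rank-then-Pearson
# Spearman oracle).
pearson_oracle <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random normalized fraction vectors for property tests.
random_fractions <- function(n, seed, cv = 0.5) {
  withr::with_seed(seed, {
    w <- stats::rlnorm(n, sdlog = sqrt(log(1 + cv^2)))
    f <- w / sum(w)
    stats::setNames(f, sprintf("L%03d", seq_len(n)))
  })
}
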