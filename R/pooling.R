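#' Acoustic-dispenser pooling constraints
#'
#' Transfer volumes on an acoustic liquid handler are built from discrete
#' droplets, so every dispense is an integer multiple of the droplet volume
#' (`quantum`, 25 nL on the Echo 525) and bounded by a practical per-transfer
#' range. The defaults mirror a 265-library re-pool spanning 160-3800 nL
#' after a 500 nL equal-volume pilot.
#'
#' Because `v_min` need not itself be a multiple of `quantum` (160 is not a
#' multiple of 25), planned volumes are kept inside the *attainable* range:
#' from the smallest multiple of `quantum` at or above `v_min` to the largest
#' multiple at or below `v_max`.
#'
#' @param v_min,v_max minimum and maximum transfer volume, nL.
#' @param quantum droplet increment, nL.
#' @param pilot_volume equal volume dispensed per library in the pilot pool,
#'   nL.
#' @return A list of class `pool_constraints`.
#' @export
pool_constraints <- function(v_min = 160, v_max = 3800, quantum = 25,
                             pilot_volume = 500) {
  if (!(v_min > 0 && v_min <= v_max)) stop("need 0 < v_min <= v_max")
  if (quantum <= 0) stop("quantum must be positive")
  if (pilot_volume < v_min || pilot_volume > v_max) {
    stop("pilot_volume must lie within [v_min, v_max]")
  }
  lo <- quantum * ceiling(v_min / quantum)
  hi <- quantum * floor(v_max / quantum)
  if (lo > hi) stop("no multiple of quantum lies within [v_min, v_max]")
  structure(list(v_min = v_min, v_max = v_max, quantum = quantum,
                 pilot_volume = pilot_volume, lo = lo, hi = hi),
            class = "pool_constraints")
}

# Nearest-multiple rounding with ties rounding up.
quantize_volume <- function(v, quantum) {
  quantum * floor(v / quantum + 0.5)
}

new_pool_plan <- function(library_id, volume, clipped_low, clipped_high,
                          quantized_from) {
  out <- data.frame(
    library_id = as.character(library_id),
    volume = as.numeric(volume),
    clipped_low = clipped_low,
    clipped_high = clipped_high,
    quantized_from = as.numeric(quantized_from),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$library_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pool_plan", "data.frame")
  out
}

#' Total volume of a pool plan
#'
#' @param plan a `pool_plan`.
#' @return Sum of per-library transfer volumes, nL.
#' @export
total_volume <- function(plan) {
  stopifnot(inherits(plan, "pool_plan"))
  sum(plan$volume)
}

#' Plan the equal-volume pilot pool
#'
#' Step one of two-step pooling: every library contributes the same
#' (quantized) pilot volume, preserving the bulk of each library while a
#' shallow calibration run measures its read share.
#'
#' @param library_ids character vector of library identifiers.
#' @param constraints a [pool_constraints] object.
#' @return A `pool_plan` data frame (columns `library_id`, `volume`,
#'   `clipped_low`, `clipped_high`, `quantized_from`).
#' @examples
#' plan <- plan_equal_volume(sprintf("L%03d", 1:265), pool_constraints())
#' total_volume(plan)  # 265 * 500 = 132500 nL
#' @export
plan_equal_volume <- function(library_ids, constraints = pool_constraints()) {
  stopifnot(inherits(constraints, "pool_constraints"))
  library_ids <- as.character(library_ids)
  if (!length(library_ids)) stop("library_ids is empty")
  if (anyDuplicated(library_ids)) stop("duplicate library_ids")
  v <- quantize_volume(constraints$pilot_volume, constraints$quantum)
  if (v < constraints$v_min || v > constraints$v_max) {
    stop("quantized pilot volume (", v, " nL) falls outside [v_min, v_max]")
  }
  new_pool_plan(library_ids, rep(v, length(library_ids)),
                clipped_low = FALSE, clipped_high = FALSE,
                quantized_from = constraints$pilot_volume)
}

#' Per-library read fractions from a pilot run
#'
#' Converts demultiplexed pilot read counts into each library's share of the
#' assigned reads (the "percent of total reads occupied by each sample").
#'
#' @param pilot_counts named non-negative numeric vector, library ID ->
#'   assigned reads.
#' @return A list of class `pilot_fractions`: `per_library` (named fractions
#'   summing to 1), `n_libraries`, `assigned_total`.
#' @export
compute_fractions <- function(pilot_counts) {
  if (is.null(names(pilot_counts)) || any(!nzchar(names(pilot_counts)))) {
    stop("pilot_counts must be a named vector of library IDs")
  }
  if (anyDuplicated(names(pilot_counts))) stop("duplicate library IDs")
  if (any(pilot_counts < 0)) stop("negative read counts")
  total <- sum(pilot_counts)
  if (total <= 0) stop("all pilot counts are zero; fractions undefined")
  structure(list(
    per_library = pilot_counts / total,
    n_libraries = length(pilot_counts),
    assigned_total = total
  ), class = "pilot_fractions")
}

#' Plan the equimolar re-pool from pilot read fractions
#'
#' Step two of two-step pooling: each library's re-pool volume is
#' proportional to the inverse of its pilot read fraction, so that (in
#' expectation) every library occupies an equal share of the deep run. Raw
#' volumes are quantized to the droplet increment (nearest multiple, ties
#' up) and clipped to the attainable range with flags.
#'
#' Under `strategy = "anchor_min"` (default) the most-abundant library is
#' anchored at the minimum attainable volume, maximizing retained material;
#' under `"fixed_total"` the raw volumes are scaled to sum to
#' `target_total`. Libraries with a zero pilot fraction carry no usable
#' abundance estimate; they are assigned the maximum volume and flagged
#' `clipped_high` rather than dropped, since low-count libraries show the
#' greatest re-pool variability.
#'
#' @param fractions a [compute_fractions] result.
#' @param constraints a [pool_constraints] object.
#' @param strategy `"anchor_min"` or `"fixed_total"`.
#' @param target_total required total volume (nL) under `"fixed_total"`.
#' @return A `pool_plan` data frame.
#' @export
plan_equimolar <- function(fractions, constraints = pool_constraints(),
                           strategy = c("anchor_min", "fixed_total"),
                           target_total = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(fractions, "pilot_fractions"),
            inherits(constraints, "pool_constraints"))
  f <- fractions$per_library
  n <- length(f)
  lo <- constraints$lo
  hi <- constraints$hi
  pos <- f > 0
  raw <- rep(NA_real_, n)
  if (any(pos)) {
    if (strategy == "anchor_min") {
      raw[pos] <- lo * max(f[pos]) / f[pos]
    } else {
      if (is.null(target_total) || target_total <= 0) {
        stop("strategy 'fixed_total' requires a positive target_total")
      }
      w <- 1 / f[pos]
      raw[pos] <- target_total * w / sum(w)
    }
  }
  vq <- ifelse(pos, quantize_volume(raw, constraints$quantum), hi)
  clipped_low <- pos & vq < lo
  clipped_high <- (pos & vq > hi) | !pos
  vol <- pmin(pmax(vq, lo), hi)
  new_pool_plan(names(f), vol, clipped_low, clipped_high,
                quantized_from = raw)
}

#' Predict deep-run read fractions for a pool plan
#'
#' Makes the "equal read representation" goal checkable before sequencing:
#' because pilot volumes were equal, each library's pilot fraction is a proxy
#' for its per-volume concentration, so its contribution to the new pool is
#' proportional to `fraction * volume`, renormalized to sum to one.
#'
#' @param fractions the pilot [compute_fractions] result.
#' @param plan a `pool_plan` covering exactly the same library set.
#' @param constraints a [pool_constraints] object (carried for provenance).
#' @return A `pilot_fractions` object of predicted deep-run fractions
#'   (`assigned_total` is `NA`; nothing has been sequenced).
#' @export
predict_fractions <- function(fractions, plan,
                              constraints = pool_constraints()) {
  stopifnot(inherits(fractions, "pilot_fractions"),
            inherits(plan, "pool_plan"))
  f <- fractions$per_library
  if (!setequal(names(f), plan$library_id) ||
      length(f) != nrow(plan)) {
    stop("plan and fractions cover different library sets")
  }
  v <- plan$volume[match(names(f), plan$library_id)]
  contrib <- f * v
  structure(list(
    per_library = contrib / sum(contrib),
    n_libraries = length(f),
    assigned_total = NA_real_
  ), class = "pilot_fractions")
}

#' Variance-ratio F test between two groups of read fractions
#'
#' Tests whether re-pooling tightened the spread of per-library read shares:
#' `F = sd_a^2 / sd_b^2` referred to the F distribution with
#' `(n_a - 1, n_b - 1)` degrees of freedom, two-sided. Either group may be
#' given as a sample of fractions or as a `list(sd =, n =)` summary, so
#' published standard deviations can be tested directly.
#'
#' @param group_a,group_b numeric vectors of per-library shares (percent or
#'   fraction, consistently), or `list(sd =, n =)` summaries.
#' @return A list of class `variance_comparison`: `sd_a`, `sd_b`, `n_a`,
#'   `n_b`, `f_statistic`, `df`, `p_value`.
#' @examples
#' # printed pilot vs re-pool spreads, 265 libraries each
#' compare_variance(list(sd = 0.125, n = 265), list(sd = 0.087, n = 265))
#' @export
compare_variance <- function(group_a, group_b) {
  as_summary <- function(g, label) {
    if (is.list(g)) {
      if (!all(c("sd", "n") %in% names(g))) {
        stop(label, ": summary form must be list(sd =, n =)")
      }
      s <- list(sd = as.numeric(g$sd), n = as.integer(g$n))
    } else {
      s <- list(sd = stats::sd(g), n = length(g))
    }
    if (s$n < 2L) stop(label, ": need n >= 2")
    if (is.na(s$sd) || s$sd < 0) stop(label, ": invalid SD")
    s
  }
  a <- as_summary(group_a, "group_a")
  b <- as_summary(group_b, "group_b")
  if (b$sd == 0) stop("zero variance in denominator group")
  f <- a$sd^2 / b$sd^2
  df <- c(a$n - 1L, b$n - 1L)
  p_lower <- stats::pf(f, df[1L], df[2L])
  p <- min(1, 2 * min(p_lower, 1 - p_lower))
  structure(list(sd_a = a$sd, sd_b = b$sd, n_a = a$n, n_b = b$n,
                 f_statistic = f, df = df, p_value = p),
            class = "variance_comparison")
}

#' Write an acoustic-dispenser transfer list
#'
#' Emits the CSV picklist the dispenser consumes: header
#' `Source Plate Name,Source Well,Destination Well,Transfer Volume`, one row
#' per library in deterministic (library ID) order, volumes as integer nL,
#' LF line endings.
#'
#' @param plan a `pool_plan`.
#' @param source_layout data frame with columns `library_id`, `plate`,
#'   `well` mapping every planned library to its source position.
#' @param destination_well destination well name for the pooled volume.
#' @param path optional output file; when `NULL` the CSV text is returned
#'   only.
#' @return Character vector of CSV lines, invisibly when written to `path`.
#' @export
write_transfer_list <- function(plan, source_layout, destination_well = "A1",
                                path = NULL) {
  stopifnot(inherits(plan, "pool_plan"), is.data.frame(source_layout))
  if (!all(c("library_id", "plate", "well") %in% names(source_layout))) {
    stop("source_layout needs columns library_id, plate, well")
  }
  idx <- match(plan$library_id, source_layout$library_id)
  if (anyNA(idx)) {
    stop("no source well for library: ",
         paste(plan$library_id[is.na(idx)], collapse = ", "))
  }
  lines <- c(
    "Source Plate Name,Source Well,Destination Well,Transfer Volume",
    paste(source_layout$plate[idx], source_layout$well[idx],
          destination_well, format(as.integer(round(plan$volume)),
                                   scientific = FALSE, trim = TRUE),
          sep = ",")
  )
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    return(invisible(lines))
  }
  lines
}

#' @export
print.pool_plan <- function(x, ...) {
  cat(sprintf("Pool plan: %d libraries, total volume %s nL\n", nrow(x),
              format(sum(x$volume), big.mark = ",", scientific = FALSE)))
  cat(sprintf("  volume range %g-%g nL; clipped low: %d, clipped high: %d\n",
              min(x$volume), max(x$volume),
              sum(x$clipped_low), sum(x$clipped_high)))
  NextMethod()
}

#' @export
print.variance_comparison <- function(x, ...) {
  cat(sprintf(
    "Variance-ratio F test: F = %.4f on (%d, %d) df, two-sided p = %.3g\n",
    x$f_statistic, x$df[1L], x$df[2L], x$p_value))
  cat(sprintf("  SD a: %.4g (n = %d)  SD b: %.4g (n = %d)\n",
              x$sd_a, x$n_a, x$sd_b, x$n_b))
  invisible(x)
}
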