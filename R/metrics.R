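#' Reads per million (rpm)
#'
#' Depth-normalized detection metric: unique reads assigned to a taxon per
#' million total sequenced reads. The denominator is whatever read total the
#' caller supplies (pre- or post-filter), so the convention is explicit at
#' the call site.
#'
#' @param unique_reads unique reads assigned to the taxon.
#' @param total_reads total sequenced reads in the library (>= 1).
#' @return `unique_reads * 1e6 / total_reads`. Vectorized.
#' @examples
#' rpm(63, 5e5)  # 126
#' @export
rpm <- function(unique_reads, total_reads) {
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  if (any(unique_reads < 0)) stop("unique_reads must be non-negative")
  if (any(unique_reads > total_reads)) {
    stop("unique_reads cannot exceed total_reads")
  }
  unique_reads * 1e6 / total_reads
}

#' Randomly downsample a count table to a fixed total
#'
#' Draws `target_total` reads without replacement from the pooled reads, so
#' each category's downsampled count follows the multivariate hypergeometric
#' distribution (marginally hypergeometric). This makes libraries sequenced
#' to different depths comparable at the depth of the shallowest.
#'
#' @param counts named non-negative integer vector (category -> reads).
#' @param target_total number of reads to keep; at most `sum(counts)`.
#' @param seed integer seed; the draw is reproducible per seed.
#' @return Named vector of downsampled counts summing to `target_total`,
#'   with each entry at most its input count.
#' @export
downsample_counts <- function(counts, target_total, seed) {
  if (is.null(names(counts))) stop("counts must be named")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (target_total > total) {
    stop("target_total (", target_total, ") exceeds available reads (",
         total, ")")
  }
  if (target_total < 0) stop("target_total must be non-negative")
  out <- counts
  withr::with_seed(seed, {
    remaining_pool <- total
    remaining_draw <- target_total
    for (i in seq_along(counts)) {
      # marginal of the multivariate hypergeometric, drawn sequentially
      x <- stats::rhyper(1L, m = counts[[i]],
                         n = remaining_pool - counts[[i]],
                         k = remaining_draw)
      out[[i]] <- x
      remaining_pool <- remaining_pool - counts[[i]]
      remaining_draw <- remaining_draw - x
    }
  })
  out
}

#' Per-base depth profile for a reference sequence
#'
#' @param reference_id reference sequence name.
#' @param depths non-negative integer vector of read depth at each 0-based
#'   position; length is the reference length.
#' @return A list of class `depth_profile`.
#' @export
depth_profile <- function(reference_id, depths) {
  if (!length(depths)) stop("empty depth vector")
  if (any(depths < 0) || any(depths != round(depths))) {
    stop("depths must be non-negative integers")
  }
  structure(list(reference_id = as.character(reference_id),
                 depths = as.numeric(depths)),
            class = "depth_profile")
}

#' Read a depth profile from a two-column TSV
#'
#' Expects a header and columns `position` (0-based) and `depth`, as
#' produced by e.g. `samtools depth`-style exports; positions absent from
#' the file get depth zero up to the maximum listed position (or
#' `reference_length` when given).
#'
#' @param path TSV file path.
#' @param reference_id name for the reference; defaults to the file name.
#' @param reference_length optional full reference length.
#' @return A [depth_profile].
#' @export
read_depth_profile <- function(path, reference_id = NULL,
                               reference_length = NULL) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("position", "depth") %in% names(tab))) {
    stop("depth file needs columns 'position' and 'depth'")
  }
  if (anyDuplicated(tab$position)) stop("duplicate positions in ", path)
  if (any(tab$position < 0)) stop("positions must be 0-based non-negative")
  len <- if (is.null(reference_length)) max(tab$position) + 1L else
    as.integer(reference_length)
  if (len <= max(tab$position)) stop("reference_length shorter than data")
  depths <- numeric(len)
  depths[tab$position + 1L] <- tab$depth
  depth_profile(reference_id %||% basename(path), depths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Coverage breadth and depth statistics
#'
#' Breadth is the percentage of reference positions covered by at least one
#' read; mean and SD of depth are computed over *all* positions, zeros
#' included (population SD), with the covered-positions-only mean reported
#' as a secondary field.
#'
#' @param profile a [depth_profile] or a bare numeric depth vector.
#' @return A list: `breadth_pct` (0-100), `mean_depth`, `sd_depth`
#'   (population SD), `mean_depth_covered` (`NaN` when nothing is covered),
#'   `length`.
#' @examples
#' coverage_stats(c(2, 2, 0, 2))  # breadth 75%, mean 1.5
#' @export
coverage_stats <- function(profile) {
  d <- if (inherits(profile, "depth_profile")) profile$depths else
    as.numeric(profile)
  if (!length(d)) stop("empty depth profile")
  if (any(d < 0)) stop("negative depths")
  m <- mean(d)
  list(
    breadth_pct = 100 * mean(d >= 1),
    mean_depth = m,
    sd_depth = sqrt(mean((d - m)^2)),
    mean_depth_covered = mean(d[d >= 1]),
    length = length(d)
  )
}

#' Spearman rank correlation between two abundance vectors
#'
#' Rank-rank agreement between, e.g., transcript abundances from two library
#' preparations of the same sample. Ties receive average ranks; the p-value
#' is the large-sample approximation.
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be constant.
#' @return A list: `rho`, `p_value`, `n`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
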