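#' Read a two-column count table (TSV)
#'
#' The single tabular dialect used throughout: tab-delimited with a header,
#' an ID column (`library_id`, `taxon_id`, `control_id`, or `id`) and a
#' count column (`reads`, `count`, or `counts`). Counts must parse as
#' non-negative integers; malformed rows are rejected with the offending
#' line number.
#'
#' @param path TSV file path.
#' @return Named numeric vector, ID -> reads.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("count table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  id_col <- intersect(c("library_id", "taxon_id", "control_id", "id"),
                      names(tab))[1L]
  count_col <- intersect(c("reads", "count", "counts"), names(tab))[1L]
  if (is.na(id_col) || is.na(count_col)) {
    stop("count table needs an ID column (library_id/taxon_id/id) and a ",
         "count column (reads/count): ", path)
  }
  vals <- tab[[count_col]]
  bad <- which(!grepl("^[0-9]+$", trimws(vals)))
  if (length(bad)) {
    stop(sprintf("line %d of %s: count '%s' is not a non-negative integer",
                 bad[1L] + 1L, path, vals[bad[1L]]))
  }
  ids <- tab[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(as.numeric(vals), ids)
}

#' Write a two-column count table (TSV)
#'
#' @param counts named numeric vector.
#' @param path output path.
#' @param id_col name for the ID column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, id_col = "library_id") {
  df <- data.frame(id = names(counts),
                   reads = format(counts, scientific = FALSE, trim = TRUE),
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, "reads")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the computational pipeline end to end
#'
#' With no pilot counts supplied, runs the fully simulated experiment
#' (synthetic libraries, pilot run, re-pool, deep run) plus an ERCC
#' dose-response fit and per-library input-mass back-calculation, and
#' returns a machine-readable report. With `pilot_counts` (a named vector
#' or a TSV path), skips simulation and plans the re-pool from the observed
#' pilot read counts. Deterministic given the config seed.
#'
#' @param config a [sim_config].
#' @param constraints a [pool_constraints] object.
#' @param pilot_counts optional named count vector or count-table path.
#' @return A list of class `pipeline_report`: `ercc_fit`, `mass_estimates`
#'   (data frame, simulation mode only), `plan_summary`, `repool_plan`,
#'   `comparison`, `sim` (the `sim_result`, simulation mode only).
#' @export
run_pipeline <- function(config = sim_config(),
                         constraints = pool_constraints(),
                         pilot_counts = NULL) {
  if (!is.null(pilot_counts)) {
    if (is.character(pilot_counts)) {
      if (!file.exists(pilot_counts)) {
        stop("pipeline input not found: ", pilot_counts)
      }
      pilot_counts <- read_count_table(pilot_counts)
    }
    fractions <- compute_fractions(pilot_counts)
    plan <- plan_equimolar(fractions, constraints)
    predicted <- predict_fractions(fractions, plan, constraints)
    report <- list(
      ercc_fit = NULL, mass_estimates = NULL,
      plan_summary = plan_summary(plan),
      repool_plan = plan,
      predicted_sd_pct = 100 * stats::sd(predicted$per_library),
      comparison = NULL, sim = NULL
    )
    return(structure(report, class = "pipeline_report"))
  }

  sim <- simulate_two_step_experiment(config, constraints)
  libs <- sim$libraries

  ref <- gen_ercc_reference(seed = config$seed)
  qc_counts <- gen_ercc_counts(
    ref, input_mass_pg = libs$input_mass_pg[1L],
    depth = max(libs$pilot_reads[1L], 1000), seed = config$seed + 5L,
    spike_mass_pg = config$ercc_spike_mass_pg)
  fit <- fit_dose_response(qc_counts, ref)

  est <- vapply(seq_len(nrow(libs)), function(i) {
    if (libs$pilot_ercc_reads[i] < 1) return(NA_real_)
    back_calculate_mass(libs$pilot_ercc_reads[i], libs$pilot_reads[i],
                        config$ercc_spike_mass_pg)$total_mass_pg
  }, numeric(1))
  mass_estimates <- data.frame(
    library_id = libs$library_id,
    true_total_mass_pg = libs$input_mass_pg + config$ercc_spike_mass_pg,
    estimated_total_mass_pg = est,
    stringsAsFactors = FALSE
  )

  structure(list(
    ercc_fit = fit,
    mass_estimates = mass_estimates,
    plan_summary = plan_summary(sim$repool_plan),
    repool_plan = sim$repool_plan,
    comparison = sim$comparison,
    sim = sim
  ), class = "pipeline_report")
}

plan_summary <- function(plan) {
  list(n_libraries = nrow(plan),
       total_volume_nl = total_volume(plan),
       n_clipped_low = sum(plan$clipped_low),
       n_clipped_high = sum(plan$clipped_high))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== mNGS pooling pipeline report ==\n")
  if (!is.null(x$ercc_fit)) print(x$ercc_fit)
  if (!is.null(x$mass_estimates)) {
    ok <- stats::complete.cases(x$mass_estimates)
    r2 <- stats::cor(x$mass_estimates$true_total_mass_pg[ok],
                     x$mass_estimates$estimated_total_mass_pg[ok])^2
    cat(sprintf("Mass back-calculation: %d/%d libraries estimable, R^2 vs truth = %.4f\n",
                sum(ok), nrow(x$mass_estimates), r2))
  }
  with(x$plan_summary, cat(sprintf(
    "Re-pool plan: %d libraries, total %s nL (%d clipped low, %d clipped high)\n",
    n_libraries, format(total_volume_nl, big.mark = ","),
    n_clipped_low, n_clipped_high)))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
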