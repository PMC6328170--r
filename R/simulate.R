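#' Simulation configuration for the two-step pooling experiment
#'
#' Defaults mirror the study conditions the planner targets: 265 libraries,
#' a shallow equal-volume pilot run of 4.5 million reads, and a deep
#' re-pooled run. Library molar concentrations are lognormal with
#' coefficient of variation 0.33 — the ratio of the published pilot spread
#' to its mean (0.125/0.377). The deep run defaults to 1e7 reads, a
#' desk-scale stand-in for a production flow cell; depths are configuration,
#' not constants. Dispensing error is multiplicative with 5% CV per
#' transfer, and 25 pg of ERCC spike-in per sample feeds the mass
#' back-calculation stages. `mean_input_mass_pg` sets the mean true RNA
#' input (500 pg, the sub-nanogram regime the protocol targets).
#'
#' @param n_libraries number of libraries pooled.
#' @param molarity_cv coefficient of variation of true library molar
#'   concentration.
#' @param pilot_depth reads in the shallow calibration run.
#' @param deep_depth reads in the deep re-pooled run.
#' @param dispense_cv relative volume error per acoustic transfer.
#' @param ercc_spike_mass_pg picograms of ERCC RNA spiked per sample.
#' @param mean_input_mass_pg mean true input RNA mass per library, pg.
#' @param seed integer seed; every stochastic stage derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_libraries = 265, molarity_cv = 0.33,
                       pilot_depth = 4.5e6, deep_depth = 1e7,
                       dispense_cv = 0.05, ercc_spike_mass_pg = 25,
                       mean_input_mass_pg = 500, seed = 1L) {
  stopifnot(n_libraries >= 1, molarity_cv >= 0, pilot_depth > 0,
            deep_depth > 0, dispense_cv >= 0, ercc_spike_mass_pg > 0,
            mean_input_mass_pg > 0)
  structure(list(
    n_libraries = as.integer(n_libraries), molarity_cv = molarity_cv,
    pilot_depth = pilot_depth, deep_depth = deep_depth,
    dispense_cv = dispense_cv, ercc_spike_mass_pg = ercc_spike_mass_pg,
    mean_input_mass_pg = mean_input_mass_pg, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic ERCC-style concentration ladder
#'
#' Lays `n_species` control concentrations on a geometric ladder spanning
#' exactly `log10_span` decades (max/min ratio `10^log10_span`), with
#' transcript lengths drawn uniformly from 250-2000 bases — the shape of the
#' 92-species, six-decade ERCC mix without reproducing the vendor's values.
#'
#' @param n_species number of control species.
#' @param log10_span decades spanned by the concentration ladder.
#' @param seed integer seed for the length draw.
#' @param conc_min smallest concentration on the ladder (attomoles/uL).
#' @return An [ercc_reference].
#' @export
gen_ercc_reference <- function(n_species = 92, log10_span = 6, seed = 1L,
                               conc_min = 0.01) {
  stopifnot(n_species >= 1, log10_span >= 0, conc_min > 0)
  step <- if (n_species == 1L) 0 else
    log10_span * (seq_len(n_species) - 1) / (n_species - 1)
  lengths <- withr::with_seed(seed,
    sample(250:2000, n_species, replace = TRUE))
  ercc_reference(
    control_id = sprintf("ERCC-%05d", seq_len(n_species)),
    concentration = conc_min * 10^step,
    length = lengths,
    subgroup = rep(LETTERS[1:4], length.out = n_species)
  )
}

#' Generate a set of libraries with dispersed molar concentrations
#'
#' True molarities are lognormal with mean 1 (arbitrary units; only ratios
#' matter for pooling) and the configured CV; true input RNA masses are
#' proportional to molarity with the configured mean, emulating libraries
#' whose yield tracks their input.
#'
#' @param config a [sim_config].
#' @return A data frame of class `library_set`: `library_id`, `molarity`,
#'   `input_mass_pg`.
#' @export
gen_library_set <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_libraries
  mol <- withr::with_seed(config$seed, {
    if (config$molarity_cv == 0) rep(1, n) else {
      sdlog <- sqrt(log(1 + config$molarity_cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  })
  out <- data.frame(
    library_id = sprintf("L%04d", seq_len(n)),
    molarity = mol,
    input_mass_pg = mol * config$mean_input_mass_pg,
    stringsAsFactors = FALSE
  )
  class(out) <- c("library_set", "data.frame")
  out
}

#' Simulate a sequencing run over pooled libraries
#'
#' Reads are assigned to barcoded libraries multinomially, with
#' probabilities proportional to each library's contribution to the pool
#' (molarity x dispensed volume).
#'
#' @param contributions named non-negative vector, library -> relative
#'   contribution; at least one must be positive.
#' @param depth total reads to draw.
#' @param seed integer seed.
#' @return Named count vector summing to `depth`.
#' @export
simulate_sequencing <- function(contributions, depth, seed) {
  if (is.null(names(contributions))) stop("contributions must be named")
  if (any(contributions < 0)) stop("negative contributions")
  if (sum(contributions) <= 0) stop("all contributions are zero")
  stopifnot(depth >= 1)
  counts <- withr::with_seed(seed,
    stats::rmultinom(1L, size = depth,
                     prob = contributions / sum(contributions)))
  stats::setNames(as.numeric(counts), names(contributions))
}

#' Simulate per-transcript ERCC counts for one library
#'
#' The expected share of reads landing on the spike-ins follows the mass
#' ratio `spike / (spike + input)`; the ERCC read total is binomial at that
#' share and is then split across transcripts multinomially with weights
#' proportional to concentration (times length, by default, reflecting that
#' fragmented-library reads scale with transcript mass rather than molarity
#' alone).
#'
#' @param ref an [ercc_reference].
#' @param input_mass_pg true sample RNA input mass, pg (0 means a blank:
#'   every read is a spike-in read).
#' @param depth total reads sequenced for the library.
#' @param seed integer seed.
#' @param spike_mass_pg spiked ERCC mass, pg.
#' @param length_weighted weight transcripts by concentration x length
#'   (default) or concentration alone.
#' @return An [ercc_counts] with `total_reads = depth`.
#' @export
gen_ercc_counts <- function(ref, input_mass_pg, depth, seed,
                            spike_mass_pg = 25, length_weighted = TRUE) {
  stopifnot(inherits(ref, "ercc_reference"), input_mass_pg >= 0,
            depth >= 1, spike_mass_pg > 0)
  share <- spike_mass_pg / (spike_mass_pg + input_mass_pg)
  w <- ref$concentration
  if (length_weighted) {
    if (anyNA(ref$length)) stop("length weighting needs transcript lengths")
    w <- w * ref$length
  }
  per <- withr::with_seed(seed, {
    n_ercc <- stats::rbinom(1L, size = depth, prob = share)
    if (n_ercc > 0) {
      as.numeric(stats::rmultinom(1L, size = n_ercc, prob = w / sum(w)))
    } else {
      numeric(nrow(ref))
    }
  })
  ercc_counts(stats::setNames(per, ref$control_id), total_reads = depth)
}

#' Run the full two-step pooling experiment in silico
#'
#' Chains the whole workflow: generate dispersed libraries, pool them at
#' equal pilot volumes, sequence the pilot multinomially, estimate read
#' fractions, plan the inverse-fraction re-pool, perturb the re-pool volumes
#' with multiplicative dispensing noise, sequence the deep run, and compare
#' the spread of per-library shares before and after re-pooling with a
#' variance-ratio F test. Per-library ERCC read totals are drawn from the
#' pilot counts at each library's mass-ratio share, so input masses can be
#' back-calculated from the same simulation.
#'
#' @param config a [sim_config].
#' @param constraints a [pool_constraints] object.
#' @return A list of class `sim_result`: `sd_equal_volume` and `sd_repooled`
#'   (per-library share SDs, percent of total reads), `comparison` (the
#'   [compare_variance] result, equal-volume spread in the numerator),
#'   `libraries` (data frame with true molarity, input mass, pilot / re-pool
#'   / pilot-ERCC read counts), `repool_plan`, and `config`.
#' @export
simulate_two_step_experiment <- function(config = sim_config(),
                                         constraints = pool_constraints()) {
  stopifnot(inherits(config, "sim_config"))
  libs <- gen_library_set(config)
  ids <- libs$library_id

  pilot_plan <- plan_equal_volume(ids, constraints)
  pilot_vol <- pilot_plan$volume[match(ids, pilot_plan$library_id)]
  pilot_counts <- simulate_sequencing(
    stats::setNames(libs$molarity * pilot_vol, ids),
    depth = config$pilot_depth, seed = config$seed + 1L)

  fractions <- compute_fractions(pilot_counts)
  repool_plan <- plan_equimolar(fractions, constraints)
  v <- repool_plan$volume[match(ids, repool_plan$library_id)]
  noise <- withr::with_seed(config$seed + 2L,
    pmax(stats::rnorm(length(v), mean = 1, sd = config$dispense_cv), 0))
  deep_counts <- simulate_sequencing(
    stats::setNames(libs$molarity * v * noise, ids),
    depth = config$deep_depth, seed = config$seed + 3L)
  deep_fractions <- compute_fractions(deep_counts)

  ercc_share <- config$ercc_spike_mass_pg /
    (config$ercc_spike_mass_pg + libs$input_mass_pg)
  ercc_reads <- withr::with_seed(config$seed + 4L,
    stats::rbinom(length(ids), size = pilot_counts[ids], prob = ercc_share))

  pct_equal <- 100 * fractions$per_library[ids]
  pct_repool <- 100 * deep_fractions$per_library[ids]
  libs$pilot_reads <- as.numeric(pilot_counts[ids])
  libs$repool_reads <- as.numeric(deep_counts[ids])
  libs$pilot_ercc_reads <- as.numeric(ercc_reads)

  structure(list(
    sd_equal_volume = stats::sd(pct_equal),
    sd_repooled = stats::sd(pct_repool),
    comparison = compare_variance(pct_equal, pct_repool),
    libraries = libs,
    repool_plan = repool_plan,
    config = config
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "Two-step pooling simulation: %d libraries, pilot %.3g / deep %.3g reads\n",
    x$config$n_libraries, x$config$pilot_depth, x$config$deep_depth))
  cat(sprintf("  per-library share SD: %.4f%% (equal volume) -> %.4f%% (re-pooled)\n",
              x$sd_equal_volume, x$sd_repooled))
  cat(sprintf("  F = %.3f, two-sided p = %.3g\n",
              x$comparison$f_statistic, x$comparison$p_value))
  invisible(x)
}
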