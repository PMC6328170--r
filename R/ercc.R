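#' Construct an ERCC reference ladder
#'
#' An `ercc_reference` is a data frame describing a set of spike-in control
#' transcripts: one row per control, with its molar concentration in the
#' spike-in mix and (optionally) its length. The External RNA Controls
#' Consortium (ERCC) mix contains 92 variable-length transcripts spanning
#' roughly six orders of magnitude of concentration; any table with the same
#' shape is accepted.
#'
#' @param control_id character vector of unique control identifiers.
#' @param concentration numeric vector of molar concentrations
#'   (attomoles/uL in the mix); strictly positive.
#' @param length integer vector of transcript lengths in bases, or `NA`
#'   when unknown (the vendor concentration file does not carry lengths).
#' @param subgroup optional character vector of concentration subgroups.
#'
#' @return A data frame of class `ercc_reference` with columns
#'   `control_id`, `concentration`, `length`, `subgroup`.
#' @export
ercc_reference <- function(control_id, concentration, length = NA_integer_,
                           subgroup = NA_character_) {
  control_id <- as.character(control_id)
  concentration <- as.numeric(concentration)
  if (anyDuplicated(control_id)) {
    stop("duplicate control_id in ERCC reference: ",
         paste(unique(control_id[duplicated(control_id)]), collapse = ", "))
  }
  if (anyNA(concentration) || any(concentration <= 0)) {
    stop("ERCC concentrations must be strictly positive")
  }
  length <- suppressWarnings(as.integer(length))
  if (any(!is.na(length) & length <= 0L)) {
    stop("ERCC transcript lengths must be positive integers")
  }
  out <- data.frame(
    control_id = control_id,
    concentration = concentration,
    length = rep_len(length, base::length(control_id)),
    subgroup = rep_len(as.character(subgroup), base::length(control_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ercc_reference", "data.frame")
  out
}

#' Read an ERCC concentration table
#'
#' Reads a tab-delimited spike-in concentration table in the vendor layout
#' (columns including `"ERCC ID"` and a Mix-1 concentration column in
#' attomoles/uL) or any layout naming an ID and a concentration column.
#' Columns are auto-detected by name unless given explicitly.
#'
#' @param path path to a tab-delimited text file with a header row.
#' @param id_col,conc_col,length_col,subgroup_col optional explicit column
#'   names; when `NULL`, matched case-insensitively (`"ERCC ID"` /
#'   `control_id` / `id` for the ID; `"Mix 1"` / `concentration` for the
#'   concentration; `length`; `subgroup`).
#'
#' @return An [ercc_reference] with one record per row.
#' @examples
#' ref_file <- system.file("extdata", "ercc_mix1_synthetic.tsv",
#'                         package = "echopool")
#' ref <- read_ercc_table(ref_file)
#' nrow(ref)  # 92
#' @export
read_ercc_table <- function(path, id_col = NULL, conc_col = NULL,
                            length_col = NULL, subgroup_col = NULL) {
  if (!file.exists(path)) stop("ERCC table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  find_col <- function(given, patterns, what, required = TRUE) {
    if (!is.null(given)) {
      if (!given %in% names(tab)) {
        stop("column '", given, "' not present in ", path)
      }
      return(given)
    }
    for (p in patterns) {
      hit <- grep(p, names(tab), ignore.case = TRUE, value = TRUE)
      if (length(hit)) return(hit[[1L]])
    }
    if (required) {
      stop("could not locate a ", what, " column in ", path,
           " (columns: ", paste(names(tab), collapse = ", "), ")")
    }
    NULL
  }
  id_col <- find_col(id_col, c("ercc.?id", "control_?id", "^id$"), "control ID")
  conc_col <- find_col(conc_col, c("mix.?1", "concentration"), "concentration")
  length_col <- find_col(length_col, "length", "length", required = FALSE)
  subgroup_col <- find_col(subgroup_col, "subgroup", "subgroup",
                           required = FALSE)
  conc <- suppressWarnings(as.numeric(tab[[conc_col]]))
  if (anyNA(conc)) stop("non-numeric concentration values in ", path)
  ercc_reference(
    control_id = tab[[id_col]],
    concentration = conc,
    length = if (is.null(length_col)) NA_integer_ else tab[[length_col]],
    subgroup = if (is.null(subgroup_col)) NA_character_ else
      tab[[subgroup_col]]
  )
}

#' Per-library ERCC read counts
#'
#' Bundles the reads assigned to each spike-in transcript in one library
#' together with the library's total sequenced reads.
#'
#' @param per_transcript named non-negative integer vector of reads per
#'   control transcript (names are control IDs).
#' @param total_reads total sequenced reads in the library; must be at least
#'   `sum(per_transcript)`.
#'
#' @return A list of class `ercc_counts` with elements `per_transcript` and
#'   `total_reads`.
#' @export
ercc_counts <- function(per_transcript, total_reads) {
  if (is.null(names(per_transcript)) || any(!nzchar(names(per_transcript)))) {
    stop("per_transcript must be a named vector of control IDs")
  }
  if (any(per_transcript < 0) || any(per_transcript != round(per_transcript))) {
    stop("per_transcript counts must be non-negative integers")
  }
  total_reads <- as.numeric(total_reads)
  if (length(total_reads) != 1L || is.na(total_reads) || total_reads < 0) {
    stop("total_reads must be a single non-negative count")
  }
  if (sum(per_transcript) > total_reads) {
    stop("sum of per-transcript ERCC reads (", sum(per_transcript),
         ") exceeds total_reads (", total_reads, ")")
  }
  structure(list(per_transcript = per_transcript, total_reads = total_reads),
            class = "ercc_counts")
}

#' Fit the ERCC dose-response
#'
#' Ordinary least-squares fit of log10(normalized read count) on
#' log10(spike-in concentration) over the detected (nonzero) transcripts.
#' A well-behaved library yields a slope near 1 and a high R^2 across the
#' ladder's six orders of magnitude; departures flag preparation problems
#' such as uneven amplification.
#'
#' Zero-count transcripts are excluded rather than pseudocounted, and their
#' number is reported through `n_detected` — adding a pseudocount would bias
#' the low end of the ladder, where dropout is expected.
#'
#' @param counts an [ercc_counts] object.
#' @param ref an [ercc_reference]; every counted transcript must appear in it.
#' @param normalization `"per_million_reads"` (default; counts per million
#'   total reads, needing no external quantification) or `"per_pg_input"`
#'   (counts per picogram of input RNA).
#' @param input_mass_pg input RNA mass in picograms; required for
#'   `normalization = "per_pg_input"`.
#'
#' @return A list of class `ercc_fit`: `slope`, `intercept` (log10-log10
#'   scale), `r_squared`, `n_detected`, `dynamic_range_log10` (decades
#'   spanned by detected transcripts), and `normalization`.
#' @export
fit_dose_response <- function(counts, ref,
                              normalization = c("per_million_reads",
                                                "per_pg_input"),
                              input_mass_pg = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(counts, "ercc_counts"), inherits(ref, "ercc_reference"))
  x <- counts$per_transcript
  missing_ids <- setdiff(names(x), ref$control_id)
  if (length(missing_ids)) {
    stop("counted transcripts absent from reference: ",
         paste(utils::head(missing_ids, 3L), collapse = ", "))
  }
  if (all(x == 0)) stop("all ERCC counts are zero; no fit possible")
  detected <- x[x > 0]
  if (length(detected) < 3L) {
    stop("insufficient detection: only ", length(detected),
         " ERCC transcripts with nonzero reads (need >= 3)")
  }
  conc <- ref$concentration[match(names(detected), ref$control_id)]
  norm <- switch(normalization,
    per_million_reads = detected / counts$total_reads * 1e6,
    per_pg_input = {
      if (is.null(input_mass_pg) || input_mass_pg <= 0) {
        stop("input_mass_pg must be supplied (and positive) for ",
             "per_pg_input normalization")
      }
      detected / input_mass_pg
    }
  )
  y <- log10(norm)
  fit <- stats::lm(y ~ log10(conc))
  # R^2 from residuals directly: a noiseless ladder is a valid input and
  # should not trip summary.lm's perfect-fit warning
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    n_detected = length(detected),
    dynamic_range_log10 = log10(max(conc) / min(conc)),
    normalization = normalization
  ), class = "ercc_fit")
}

#' Back-calculate input RNA mass from spike-in read share
#'
#' Because a known mass of ERCC RNA is added to every sample, the share of
#' reads aligning to the spike-ins measures the total RNA mass entering
#' library preparation:
#' `spike_mass / total_mass = ercc_reads / total_reads`,
#' so `total_mass = spike_mass * total_reads / ercc_reads`. The sample's own
#' mass is the total minus the spike.
#'
#' @param ercc_reads reads aligned to ERCC transcripts (>= 1; a library with
#'   no detected spike-in reads has no estimable mass).
#' @param total_reads total sequenced reads (>= `ercc_reads`).
#' @param spike_mass_pg picograms of ERCC RNA added per sample (default 25).
#'
#' @return A list of class `mass_estimate`: `total_mass_pg`,
#'   `sample_mass_pg`, `spike_fraction`, `spike_mass_pg`.
#' @examples
#' back_calculate_mass(1000, 1e6)  # 25 pg spike -> 25,000 pg total
#' @export
back_calculate_mass <- function(ercc_reads, total_reads, spike_mass_pg = 25) {
  if (length(ercc_reads) != 1L || is.na(ercc_reads) || ercc_reads < 1) {
    stop("mass not estimable: no ERCC reads detected (ercc_reads must be >= 1)")
  }
  if (total_reads < ercc_reads) {
    stop("total_reads (", total_reads, ") must be >= ercc_reads (",
         ercc_reads, ")")
  }
  if (spike_mass_pg <= 0) stop("spike_mass_pg must be positive")
  total_mass <- spike_mass_pg * total_reads / ercc_reads
  structure(list(
    total_mass_pg = total_mass,
    sample_mass_pg = total_mass - spike_mass_pg,
    spike_fraction = ercc_reads / total_reads,
    spike_mass_pg = spike_mass_pg
  ), class = "mass_estimate")
}

#' @export
print.ercc_fit <- function(x, ...) {
  cat("ERCC dose-response fit (", x$normalization, ")\n", sep = "")
  cat(sprintf("  slope: %.4f  intercept: %.4f  R-squared: %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  detected transcripts: %d  dynamic range: %.2f decades\n",
              x$n_detected, x$dynamic_range_log10))
  invisible(x)
}

#' @export
print.mass_estimate <- function(x, ...) {
  cat(sprintf(
    "Input mass estimate: total %.1f pg (sample %.1f pg + spike %.1f pg)\n",
    x$total_mass_pg, x$sample_mass_pg, x$spike_mass_pg))
  cat(sprintf("  spike-in read fraction: %.4g\n", x$spike_fraction))
  invisible(x)
}
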