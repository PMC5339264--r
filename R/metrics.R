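# Scaling metrics: weak scaling efficiency (WSE), speedup, per-molecule
# docking-time histograms, and WSE estimation from aggregate benchmark
# figures when only totals are published.

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Render a fraction as an integer percent
#'
#' Rounds half away from zero, the convention used when quoting scaling
#' efficiencies like "85%".
#'
#' @param x Fraction (e.g. 0.8545).
#' @return Character, e.g. `"85%"`.
#' @export
percent <- function(x) {
  sprintf("%d%%", as.integer(round_half_up(100 * x)))
}

#' A weak-scaling observation
#'
#' One benchmark run: `work_units` units of input processed by
#' `processing_elements` parallel processing elements in `wall_time` seconds.
#' For weak scaling the input grows with the resources, so `work_units`
#' matches `processing_elements`.
#'
#' @param work_units Positive integer.
#' @param processing_elements Positive integer.
#' @param wall_time Positive wall-clock seconds.
#' @return An object of class `scaling_observation`.
#' @export
scaling_observation <- function(work_units, processing_elements, wall_time) {
  if (!(work_units >= 1 && processing_elements >= 1 && wall_time > 0))
    ds_error("domain", "all scaling-observation fields must be positive")
  structure(list(work_units = as.integer(work_units),
                 processing_elements = as.integer(processing_elements),
                 wall_time = as.numeric(wall_time)),
            class = "scaling_observation")
}

#' Weak scaling efficiency
#'
#' The running time for one processing element to process one work unit,
#' divided by the running time for N processing elements to process N work
#' units. 1.0 is perfect weak scaling; values above 1 (superlinear) are
#' permitted.
#'
#' @param baseline A [scaling_observation()] with `work_units = 1`.
#' @param scaled A [scaling_observation()] with
#'   `work_units == processing_elements`.
#' @return The WSE fraction. Use [percent()] to render it.
#' @export
wse <- function(baseline, scaled) {
  stopifnot(inherits(baseline, "scaling_observation"),
            inherits(scaled, "scaling_observation"))
  if (baseline$work_units != 1L)
    ds_error("domain", "baseline observation must have work_units = 1")
  if (scaled$work_units != scaled$processing_elements)
    ds_error("domain",
             "scaled observation must have work_units = processing_elements")
  baseline$wall_time / scaled$wall_time
}

#' Speedup T1 / TN
#'
#' How much faster the computation completes at parallelism N: the total
#' serial time divided by the parallel wall time.
#'
#' @param t1 Total serial seconds (sum of per-task times).
#' @param tn Parallel wall-clock seconds at parallelism N.
#' @return The speedup ratio.
#' @export
speedup <- function(t1, tn) {
  if (!(is.numeric(t1) && is.numeric(tn) && t1 > 0 && tn > 0))
    ds_error("domain", "t1 and tn must be positive")
  t1 / tn
}

#' Estimate weak scaling efficiency from aggregate benchmark figures
#'
#' Published benchmarks often report only totals: library size, parallelism
#' level, total serial time and parallel wall time. This estimator derives a
#' per-processing-element work unit and its serial time, then divides by the
#' parallel wall time: `work_unit_size = round(n_molecules / parallelism)`
#' molecules, `per_molecule_time = round(total_serial_time / n_molecules)`
#' seconds (both rounded half away from zero, mirroring how such figures are
#' quoted), `work_unit_time = work_unit_size * per_molecule_time`, and
#' `wse = work_unit_time / parallel_time`. Unrounded intermediates are
#' retained alongside.
#'
#' @param n_molecules Number of molecules screened.
#' @param parallelism Parallelism level (processing elements).
#' @param total_serial_time Total serial time, seconds.
#' @param parallel_time Parallel wall time, seconds.
#' @return An `efficiency_estimate`: `work_unit_size` (molecules),
#'   `per_molecule_time` (s), `work_unit_time` (s), `wse` (fraction), `t1`,
#'   `tn`, `speedup`, plus `work_unit_size_raw` and `per_molecule_time_raw`.
#' @export
estimate_wse_from_aggregates <- function(n_molecules, parallelism,
                                         total_serial_time, parallel_time) {
  if (!(n_molecules > 0 && parallelism > 0 && total_serial_time > 0 &&
        parallel_time > 0))
    ds_error("domain", "all inputs must be positive")
  if (parallelism > n_molecules)
    ds_warning("domain",
               "parallelism exceeds molecule count; work unit may round to 0")
  wus_raw <- n_molecules / parallelism
  wus <- as.integer(round_half_up(wus_raw))
  if (wus < 1L)
    ds_error("domain", "work-unit size rounds to 0 molecules")
  pmt_raw <- total_serial_time / n_molecules
  pmt <- round_half_up(pmt_raw)
  wut <- wus * pmt
  structure(
    list(work_unit_size = wus, work_unit_size_raw = wus_raw,
         per_molecule_time = pmt, per_molecule_time_raw = pmt_raw,
         work_unit_time = wut, wse = wut / parallel_time,
         t1 = total_serial_time, tn = parallel_time,
         speedup = total_serial_time / parallel_time),
    class = "efficiency_estimate"
  )
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf(
    paste0("Aggregate weak-scaling estimate\n",
           "  work unit:         %d molecules (%.3f unrounded)\n",
           "  per-molecule time: %d s (%.3f unrounded)\n",
           "  work-unit time:    %d s\n",
           "  WSE:               %s (%.4f)\n",
           "  speedup T1/TN:     %.1f\n"),
    x$work_unit_size, x$work_unit_size_raw,
    as.integer(x$per_molecule_time), x$per_molecule_time_raw,
    as.integer(x$work_unit_time), percent(x$wse), x$wse, x$speedup))
  invisible(x)
}

#' Histogram of per-molecule docking times
#'
#' Divides the observed times into `bins` equally spaced bins spanning the
#' data range; every bin is left-closed and the last is closed on both
#' sides, so the counts always sum to the number of observations. When all
#' times are identical the (zero-width) range is widened to one unit around
#' the value so the single occupied bin is well defined.
#'
#' @param times Numeric vector of seconds (non-empty, finite).
#' @param bins Number of bins (default 20).
#' @return Data frame with columns `lower`, `upper`, `count`.
#' @export
time_histogram <- function(times, bins = 20L) {
  bins <- as.integer(bins)
  if (!length(times) || any(!is.finite(times)))
    ds_error("domain", "times must be non-empty and finite")
  if (is.na(bins) || bins < 1L)
    ds_error("domain", "bins must be >= 1")
  r <- range(times)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  breaks <- seq(r[1], r[2], length.out = bins + 1L)
  idx <- findInterval(times, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  data.frame(lower = breaks[-(bins + 1L)], upper = breaks[-1L],
             count = tabulate(idx, nbins = bins))
}

strip_timing_tags <- function(rec) {
  rec$tags <- rec$tags[setdiff(names(rec$tags), "DockingTimeSeconds")]
  rec
}

#' Validate that serial and parallel screening agree
#'
#' Draws a seeded random sample from the library, screens it serially
#' (parallelism 1) and in parallel, and compares the ID-sorted pose sets
#' field by field (ID, connection table, all tags except the per-pose timing
#' annotation). This is the standard correctness check for a parallelised
#' screening pipeline: the parallel output must not differ from the serial
#' one.
#'
#' @param library SDF path or list of [molecule_record()] objects.
#' @param backend Backend command vector; default the mock backend.
#' @param parallelism Parallel slot count for the parallel run (default 4).
#' @param sample_size Molecules to draw (without replacement).
#' @param seed Integer seed for the sampler.
#' @param chunk_size Chunk size for both runs (default 30).
#' @return A `validation_report`: `pass`, `n_compared`, `first_mismatch`
#'   (ID or `NA`), `detail`.
#' @export
validate_equivalence <- function(library, backend = mock_backend_command(),
                                 parallelism = 4L, sample_size = 1000L,
                                 seed = 1L, chunk_size = 30L) {
  records <- if (is.character(library) && length(library) == 1L)
    parse_sdf(library) else library
  if (sample_size > length(records))
    ds_error("domain", "sample_size exceeds library size")
  sampled <- sample_molecules(records, sample_size, seed)

  report <- function(pass, n, first_mismatch, detail) {
    structure(list(pass = pass, n_compared = n,
                   first_mismatch = first_mismatch, detail = detail),
              class = "validation_report")
  }
  if (sample_size == 0L)
    return(report(TRUE, 0L, NA_character_, "empty comparison"))

  run_once <- function(par) {
    dir <- tempfile("dockscreen-validate-")
    cfg <- pipeline_config(parallelism = par, chunk_size = chunk_size,
                           checkpoint_dir = file.path(dir, "checkpoint"))
    run_screen(sampled, backend, cfg)$poses
  }
  serial <- run_once(1L)
  par <- run_once(parallelism)
  if (length(serial) != length(par))
    return(report(FALSE, length(serial), NA_character_,
                  sprintf("pose counts differ: %d serial vs %d parallel",
                          length(serial), length(par))))

  sort_by_id <- function(poses) {
    ids <- vapply(poses, function(p) p$id, character(1))
    lapply(poses[order(ids, method = "radix")], strip_timing_tags)
  }
  s <- sort_by_id(serial)
  p <- sort_by_id(par)
  for (i in seq_along(s)) {
    same <- identical(s[[i]]$id, p[[i]]$id) &&
      identical(s[[i]]$ctab, p[[i]]$ctab) &&
      identical(s[[i]]$tags, p[[i]]$tags)
    if (!same)
      return(report(FALSE, length(s), s[[i]]$id,
                    sprintf("first differing pose: %s", s[[i]]$id)))
  }
  report(TRUE, length(s), NA_character_,
         sprintf("%d ID-sorted poses identical", length(s)))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Serial/parallel equivalence: %s (%s)\n",
              if (x$pass) "PASS" else "FAIL", x$detail))
  invisible(x)
}
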