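#' Pipeline configuration
#'
#' Execution parameters for a screening run: how many concurrent execution
#' slots to use, how molecules are chunked, how chunk failures are retried
#' and escalated, and where poses are checkpointed.
#'
#' @param parallelism Number of concurrent execution slots (>= 1).
#' @param chunk_size Molecules per docking-executable invocation; default 30.
#' @param retries Retries per failed chunk before escalation; default 2.
#' @param on_failure `"fail_fast"` (abort, partial checkpoint preserved) or
#'   `"quarantine"` (failed chunks written to a quarantine SDF, run
#'   completes).
#' @param checkpoint_dir Directory where poses are checkpointed as part
#'   files.
#' @param timeout Per-chunk timeout in seconds; `NULL` (default) means
#'   unbounded, as docking time is in general unbounded.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(parallelism = 1L, chunk_size = 30L, retries = 2L,
                            on_failure = c("fail_fast", "quarantine"),
                            checkpoint_dir = file.path(tempdir(), "checkpoint"),
                            timeout = NULL) {
  parallelism <- as.integer(parallelism)
  retries <- as.integer(retries)
  if (is.na(parallelism) || parallelism < 1L)
    ds_error("config", "parallelism must be >= 1")
  if (is.na(retries) || retries < 0L)
    ds_error("config", "retries must be >= 0")
  chunk_size <- chunking_config(chunk_size)$chunk_size
  structure(
    list(parallelism = parallelism, chunk_size = chunk_size,
         retries = retries, on_failure = match.arg(on_failure),
         checkpoint_dir = checkpoint_dir, timeout = timeout),
    class = "pipeline_config"
  )
}

engine_log <- function(fmt, ...) {
  cat(sprintf(paste0("[dockscreen] ", fmt, "\n"), ...), file = stderr())
}

#' Pipe one chunk of molecules through a docking backend
#'
#' Serialises the chunk's records to the backend's standard input (which is
#' then closed), reads standard output to end-of-stream, and parses it as SDF
#' poses; standard error is forwarded to the engine log. The exchange with
#' the backend uses only its standard streams — the backend never reads or
#' writes intermediate files. A nonzero exit status, an output parse failure,
#' or a timeout counts as one failed attempt; after `retries + 1` attempts a
#' chunk-failure condition is raised.
#'
#' @param chunk An `sdf_chunk` from [chunk_records()].
#' @param command Character vector: program and arguments.
#' @param timeout Seconds per attempt; `NULL` = unbounded.
#' @param retries Retries after the first failed attempt (default 0).
#' @param allow_partial Accept fewer output poses than input records
#'   (default `FALSE`: a backend dropping molecules is a failure).
#' @return A `chunk_result`: fields `index`, `poses`, `attempts`, `elapsed`
#'   (wall seconds of the successful attempt).
#' @export
pipe_chunk <- function(chunk, command, timeout = NULL, retries = 0L,
                       allow_partial = FALSE) {
  stopifnot(inherits(chunk, "sdf_chunk"), is.character(command),
            length(command) >= 1L)
  retries <- as.integer(retries)
  stopifnot(retries >= 0L)
  input_lines <- unlist(lapply(chunk$records,
                               function(r) c(record_lines(r), "$$$$")),
                        use.names = FALSE)
  # Child backends written in R must resolve this package from the same
  # library tree as the parent session.
  env <- paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = ":")))
  last_err <- "unknown failure"
  for (attempt in seq_len(retries + 1L)) {
    t0 <- Sys.time()
    err_file <- tempfile("dockscreen-stderr-")
    out <- tryCatch(
      suppressWarnings(system2(
        command[1L], args = shQuote(command[-1L]), stdout = TRUE,
        stderr = err_file, stdin = "", input = input_lines, env = env,
        timeout = if (is.null(timeout)) 0 else timeout
      )),
      error = function(e) structure(character(0), status = -1L,
                                    errmsg = conditionMessage(e))
    )
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (file.exists(err_file)) {
      errs <- readLines(err_file, warn = FALSE)
      unlink(err_file)
      for (l in errs) engine_log("chunk %d [backend] %s", chunk$index, l)
    }
    status <- attr(out, "status")
    if (!is.null(status) && status != 0L) {
      last_err <- sprintf("backend exit status %d%s", status,
                          if (!is.null(attr(out, "errmsg")))
                            paste0(" (", attr(out, "errmsg"), ")") else "")
      engine_log("chunk %d attempt %d failed: %s", chunk$index, attempt,
                 last_err)
      next
    }
    poses <- tryCatch(parse_sdf(as.character(out), chunking_config()),
                      dockscreen_error = function(e) e)
    if (inherits(poses, "condition")) {
      last_err <- sprintf("output parse failure: %s", conditionMessage(poses))
      engine_log("chunk %d attempt %d failed: %s", chunk$index, attempt,
                 last_err)
      next
    }
    if (length(poses) == 0L ||
        (!allow_partial && length(poses) != length(chunk$records))) {
      last_err <- sprintf("backend returned %d poses for %d molecules",
                          length(poses), length(chunk$records))
      engine_log("chunk %d attempt %d failed: %s", chunk$index, attempt,
                 last_err)
      next
    }
    return(structure(
      list(index = chunk$index, poses = poses, attempts = attempt,
           elapsed = elapsed),
      class = "chunk_result"
    ))
  }
  stop(errorCondition(
    sprintf("chunk %d failed after %d attempt(s): %s",
            chunk$index, retries + 1L, last_err),
    chunk_index = chunk$index, attempts = retries + 1L,
    records = chunk$records,
    class = c("dockscreen_chunk_failure", "dockscreen_error")
  ))
}

#' Checkpoint poses as SDF part files
#'
#' Writes the pose sequence, split contiguously in input order across
#' `partitions` part files named `part-00000.sdf`, `part-00001.sdf`, ...,
#' followed by a zero-byte `_SUCCESS` marker — the layout distributed
#' text-save primitives use, so re-reading all parts in name order
#' reproduces the sequence. Refuses to write into a non-empty directory.
#'
#' @param poses List of [molecule_record()] poses.
#' @param dir Target directory (created if needed; must be empty).
#' @param partitions Number of part files (empty parts are not written).
#' @return Character vector of part-file paths, invisibly.
#' @export
checkpoint <- function(poses, dir, partitions = 1L) {
  partitions <- as.integer(partitions)
  stopifnot(partitions >= 1L)
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                           no.. = TRUE)))
    ds_error("io", sprintf(
      "checkpoint directory exists and is not empty: %s", dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(poses)
  paths <- character(0)
  if (n > 0L) {
    p_eff <- min(partitions, n)
    bounds <- floor(seq(0, n, length.out = p_eff + 1L))
    for (i in seq_len(p_eff)) {
      path <- file.path(dir, sprintf("part-%05d.sdf", i - 1L))
      write_sdf(poses[(bounds[i] + 1L):bounds[i + 1L]], path)
      paths <- c(paths, path)
    }
  }
  stopifnot(file.create(file.path(dir, "_SUCCESS")))
  invisible(paths)
}

#' Re-read a checkpoint directory
#'
#' @param dir A directory written by [checkpoint()].
#' @return List of [molecule_record()] poses in checkpoint order.
#' @export
read_checkpoint <- function(dir) {
  if (!dir.exists(dir))
    ds_error("io", sprintf("checkpoint directory not found: %s", dir))
  if (!file.exists(file.path(dir, "_SUCCESS")))
    ds_warning("io", sprintf("checkpoint %s has no _SUCCESS marker", dir))
  parts <- sort(list.files(dir, pattern = "^part-[0-9]{5}\\.sdf$",
                           full.names = TRUE))
  do.call(c, c(lapply(parts, parse_sdf), list(list())))
}

#' Make an auxiliary file available to every execution slot
#'
#' Registers a receptor or other auxiliary file and returns a handle (an
#' absolute path) that every backend invocation can resolve to identical
#' content. Sharing the same file twice returns the same handle.
#'
#' @param path Existing readable file.
#' @return The shared handle (normalised absolute path).
#' @export
share_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    ds_error("config", sprintf("cannot share missing file: %s", path))
  handle <- normalizePath(path, winslash = "/", mustWork = TRUE)
  if (is.null(.ds_state$shared)) .ds_state$shared <- character(0)
  if (!handle %in% .ds_state$shared)
    .ds_state$shared <- c(.ds_state$shared, handle)
  handle
}

#' @rdname share_file
#' @return `shared_files()` returns all registered handles.
#' @export
shared_files <- function() {
  if (is.null(.ds_state$shared)) character(0) else .ds_state$shared
}

#' Run a full screening pass over a molecular library
#'
#' Parses the library, chunks it, dispatches the chunks across
#' `config$parallelism` execution slots with dynamic assignment, retries
#' failed chunks, and checkpoints all poses in chunk-index order (so the
#' checkpoint is reproducible regardless of completion order). The multiset
#' of output poses is independent of the parallelism level.
#'
#' @param library SDF file path or a list of [molecule_record()] objects.
#' @param backend Character vector: backend program and arguments (see
#'   [mock_backend_command()], [make_backend_command()]).
#' @param config A [pipeline_config()].
#' @return A `screen_run` object: `manifest` (data frame with per-chunk
#'   size, attempts, elapsed seconds and status), `poses`, `checkpoint_dir`,
#'   `part_files`, and `quarantine` (path or `NA`).
#' @export
run_screen <- function(library, backend, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- if (is.character(library) && length(library) == 1L) {
    if (!file.exists(library))
      ds_error("io", sprintf("library file not found: %s", library))
    parse_sdf(library)
  } else library
  chunks <- chunk_records(records, config$chunk_size)
  engine_log("screening %d molecules in %d chunk(s), parallelism %d",
             length(records), length(chunks), config$parallelism)

  worker <- function(ch) {
    tryCatch(
      pipe_chunk(ch, backend, timeout = config$timeout,
                 retries = config$retries),
      dockscreen_chunk_failure = function(e) e
    )
  }
  results <- if (config$parallelism > 1L && length(chunks) > 1L) {
    parallel::mclapply(chunks, worker, mc.cores = config$parallelism,
                       mc.preschedule = FALSE)
  } else {
    lapply(chunks, worker)
  }

  ok <- vapply(results, inherits, logical(1), what = "chunk_result")
  manifest <- data.frame(
    chunk = vapply(chunks, function(ch) ch$index, integer(1)),
    n_records = vapply(chunks, function(ch) length(ch$records), integer(1)),
    attempts = vapply(seq_along(results), function(i) {
      r <- results[[i]]
      if (ok[i]) r$attempts
      else if (!is.null(r$attempts)) as.integer(r$attempts)
      else config$retries + 1L
    }, integer(1)),
    elapsed = vapply(seq_along(results), function(i)
      if (ok[i]) results[[i]]$elapsed else NA_real_, numeric(1)),
    status = ifelse(ok, "ok", "failed"),
    stringsAsFactors = FALSE
  )

  poses <- do.call(c, c(lapply(results[ok], function(r) r$poses),
                        list(list())))
  quarantine <- NA_character_

  if (any(!ok)) {
    msgs <- vapply(results[!ok], conditionMessage, character(1))
    if (config$on_failure == "fail_fast") {
      checkpoint(poses, config$checkpoint_dir, config$parallelism)
      stop(errorCondition(
        sprintf("screening aborted, %d chunk(s) failed (partial checkpoint in %s): %s",
                sum(!ok), config$checkpoint_dir, msgs[1L]),
        manifest = manifest,
        class = c("dockscreen_run_failure", "dockscreen_error")
      ))
    }
    quarantine <- file.path(dirname(config$checkpoint_dir), "quarantine.sdf")
    dir.create(dirname(quarantine), recursive = TRUE, showWarnings = FALSE)
    failed_records <- do.call(c, c(lapply(which(!ok), function(i)
      chunks[[i]]$records), list(list())))
    write_sdf(failed_records, quarantine)
    engine_log("%d failed chunk(s) quarantined to %s", sum(!ok), quarantine)
  }

  part_files <- checkpoint(poses, config$checkpoint_dir, config$parallelism)
  structure(
    list(manifest = manifest, poses = poses,
         checkpoint_dir = config$checkpoint_dir,
         part_files = part_files, quarantine = quarantine),
    class = "screen_run"
  )
}

#' @export
print.screen_run <- function(x, ...) {
  cat(sprintf("<screen_run: %d poses, %d chunk(s) (%d failed), checkpoint %s>\n",
              length(x$poses), nrow(x$manifest),
              sum(x$manifest$status == "failed"), x$checkpoint_dir))
  invisible(x)
}
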