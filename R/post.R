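# Top-N hit selection without a distributed sort of full SDF blocks:
# lightweight (ID, score) pairs are collected, sorted serially in memory,
# and only then are the corresponding full poses retrieved by ID from the
# checkpoint with a scan-and-filter pass.

#' Collect lightweight ID/score pairs from poses
#'
#' One entry per pose, in source order; only the ID and the numeric `Score`
#' tag are retained, never the SDF block, so the subsequent sort touches
#' small tuples only.
#'
#' @param poses List of scored [molecule_record()] poses, or a checkpoint
#'   directory path (read with [read_checkpoint()]).
#' @return Data frame with columns `id` (character) and `score` (numeric).
#' @export
collect_scores <- function(poses) {
  if (is.character(poses) && length(poses) == 1L)
    poses <- read_checkpoint(poses)
  stopifnot(is.list(poses))
  data.frame(
    id = vapply(poses, function(p) p$id, character(1)),
    score = vapply(poses, pose_score, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Select the top-N scoring entries
#'
#' Sorts entries by score descending, ties broken by ID ascending (byte
#' order, so the result is locale-independent), and returns the first
#' `min(n, count)`. Duplicate IDs are resolved to the higher-scoring entry
#' with a warning.
#'
#' @param entries Data frame with columns `id` and `score` (finite).
#' @param n Number of hits to keep (>= 1).
#' @return Data frame of at most `n` rows, ordered best-first.
#' @export
top_n <- function(entries, n = 10L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L)
    ds_error("config", "n must be >= 1")
  stopifnot(is.data.frame(entries), all(c("id", "score") %in% names(entries)))
  if (nrow(entries) == 0L) return(entries[, c("id", "score")])
  if (any(!nzchar(entries$id)) || any(!is.finite(entries$score)))
    ds_error("data", "entries must have non-empty ids and finite scores")
  if (anyDuplicated(entries$id)) {
    dups <- unique(entries$id[duplicated(entries$id)])
    ds_warning("data", sprintf(
      "duplicate pose ID(s) %s: keeping the higher-scoring entry",
      paste(utils::head(dups, 5L), collapse = ", ")))
    best <- tapply(entries$score, entries$id, max)
    entries <- data.frame(id = names(best), score = as.numeric(best),
                          stringsAsFactors = FALSE)
  }
  ord <- order(-entries$score, entries$id, method = "radix")
  out <- entries[utils::head(ord, n), c("id", "score")]
  rownames(out) <- NULL
  out
}

#' Retrieve full poses by ID from a checkpoint
#'
#' Scan-and-filter over the checkpoint part files: full SDF blocks are read
#' once and filtered against the requested ID set; no sort of full blocks is
#' ever performed. Results are returned in the order of `ids`.
#'
#' @param checkpoint Checkpoint directory path or a list of poses.
#' @param ids Character vector of distinct molecule IDs.
#' @return List of [molecule_record()] poses, one per requested ID.
#' @export
retrieve_poses <- function(checkpoint, ids) {
  stopifnot(is.character(ids))
  if (anyDuplicated(ids))
    ds_error("config", "requested IDs must be distinct")
  if (!length(ids)) return(list())
  poses <- if (is.character(checkpoint)) read_checkpoint(checkpoint)
  else checkpoint
  keep <- Filter(function(p) p$id %in% ids, poses)
  found <- vapply(keep, function(p) p$id, character(1))
  missing <- setdiff(ids, found)
  if (length(missing))
    ds_error("missing_hit", sprintf(
      "requested ID(s) absent from checkpoint: %s",
      paste(missing, collapse = ", ")))
  keep[match(ids, found)]
}

#' Write a tab-separated top-hit report
#'
#' @param entries Ordered data frame from [top_n()].
#' @param path Output path.
#' @return The path, invisibly. Columns: `rank`, `id`, `score`.
#' @export
write_hit_report <- function(entries, path) {
  out <- data.frame(rank = seq_len(nrow(entries)), id = entries$id,
                    score = entries$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
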