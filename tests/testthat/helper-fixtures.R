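# Shared fixtures and independent oracles.

# CRC-32 (IEEE) reference values, frozen from an independent zlib
# implementation before the package's own CRC code was written.
CRC_REF <- c(
  MOL000001 = 1161931617,
  MOL000002 = 3695770331,
  MOL000003 = 2874133069,
  MOL000010 = 727558838,
  ABC = 2743272264,
  A = 3554254475
)

tmp_library <- function(n, max_chain_length = 20L, id_prefix = "MOL") {
  path <- tempfile(fileext = ".sdf")
  generate_library(n, path, max_chain_length, id_prefix)
  path
}

# Backend that always fails, for retry/escalation tests.
failing_backend <- function() {
  path <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo 'simulated docking failure' >&2",
               "exit 1"), path)
  Sys.chmod(path, "0755")
  path
}

# Mock backend whose output for one target molecule depends on the worker
# process ID, so independent runs disagree on exactly that pose.
corrupting_backend <- function(target_id) {
  script <- tempfile(fileext = ".R")
  writeLines(c(
    "suppressPackageStartupMessages(library(dockscreen))",
    'recs <- parse_sdf(file("stdin", open = "rt"))',
    "poses <- mock_dock(recs)",
    sprintf('target <- "%s"', target_id),
    "poses <- lapply(poses, function(p)",
    '  if (p$id == target) set_tag(p, "Score", sprintf("%d.000", Sys.getpid()))',
    "  else p)",
    "write_sdf(poses, stdout())"
  ), script)
  c(file.path(R.home("bin"), "Rscript"), "--vanilla", script)
}

# Independent top-N oracle: repeated extraction of the best remaining entry
# (maximum score; lowest ID among ties, byte order). Deliberately a
# different algorithm from the implementation's single vectorised sort.
oracle_top_n <- function(entries, n) {
  remaining <- entries
  rows <- list()
  while (length(rows) < n && nrow(remaining) > 0L) {
    best <- which(remaining$score == max(remaining$score))
    ids <- remaining$id[best]
    pick <- best[ids == ids[order(ids, method = "radix")[1L]]][1L]
    rows[[length(rows) + 1L]] <- remaining[pick, ]
    remaining <- remaining[-pick, ]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_entries <- function(n, seed) {
  set.seed(seed)
  data.frame(
    id = sprintf("Z%05d", sample.int(99999L, n)),
    score = round(stats::runif(n, -10, 10), 2),
    stringsAsFactors = FALSE
  )
}
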