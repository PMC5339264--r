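# Mock docking backend and the external-executable contract.
#
# Backend contract (normative): a backend reads all of standard input as
# multi-record SDF, writes one scored SDF record per input record to standard
# output in input order, exits 0 on success, and writes diagnostics to
# standard error only.

.ds_state <- new.env(parent = emptyenv())

# 32-bit unsigned arithmetic on doubles (exact below 2^53). base's bitwXor
# works on signed 32-bit integers only, so values with the high bit set are
# handled as two 16-bit halves.
bxor32 <- function(a, b) {
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
  hi * 65536 + lo
}

crc32_table <- function() {
  if (!is.null(.ds_state$crc_table)) return(.ds_state$crc_table)
  poly <- 3988292384  # 0xEDB88320, reflected IEEE 802.3 polynomial
  tab <- numeric(256)
  for (i in 0:255) {
    crc <- i
    for (k in 1:8) {
      crc <- if (crc %% 2 == 1) bxor32(crc %/% 2, poly) else crc %/% 2
    }
    tab[i + 1] <- crc
  }
  .ds_state$crc_table <- tab
  tab
}

#' CRC-32 checksum of character strings
#'
#' Table-driven CRC-32 with the IEEE 802.3 (reflected) polynomial over the
#' ASCII bytes of each string — the exactly-specified, runtime-independent
#' hash the mock docking backend derives scores and simulated times from.
#'
#' @param x Character vector.
#' @return Numeric vector of unsigned 32-bit checksums.
#' @export
crc32 <- function(x) {
  stopifnot(is.character(x))
  tab <- crc32_table()
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(s))
    crc <- 4294967295  # 0xFFFFFFFF
    for (b in bytes) {
      crc <- bxor32(crc %/% 256, tab[bxor32(crc %% 256, b) + 1])
    }
    bxor32(crc, 4294967295)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Count heavy atoms in a molecule record
#'
#' Heavy atoms are the entries of the V2000 atom block whose element symbol
#' is not `"H"`. The atom block is located from the counts line (line 4).
#'
#' @param record A [molecule_record()].
#' @return Integer count.
#' @export
heavy_atom_count <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  lines <- strsplit(record$ctab, "\n", fixed = TRUE)[[1]]
  natoms <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
  if (is.na(natoms))
    natoms <- suppressWarnings(as.integer(
      strsplit(trimws(lines[4L]), "[[:space:]]+")[[1]][1L]))
  if (is.na(natoms) || natoms < 0L || length(lines) < 4L + natoms)
    ds_error("format", sprintf(
      "record %s: atom block inconsistent with counts line", record$id))
  if (natoms == 0L) return(0L)
  syms <- vapply(lines[4L + seq_len(natoms)], function(l) {
    toks <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    if (length(toks) < 4L)
      ds_error("format", sprintf("record %s: malformed atom line", record$id))
    toks[4L]
  }, character(1), USE.NAMES = FALSE)
  sum(syms != "H")
}

mock_score_value <- function(id, heavy) heavy + (crc32(id) %% 1000) / 1000

mock_time_value <- function(id, t_min, t_max) {
  t_min + (crc32(id) %% 1001) / 1000 * (t_max - t_min)
}

#' Deterministic mock docking of molecule records
#'
#' Stands in for a docking program so the full pipeline runs without docking
#' software. Each record gets a `Score` tag equal to its heavy-atom count
#' plus `(CRC32(id) mod 1000)/1000`, and a `DockingTimeSeconds` tag equal to
#' `t_min + (CRC32(id) mod 1001)/1000 * (t_max - t_min)` — a pure function of
#' the record, identical across runs, machines and parallelism levels. Both
#' tags are written with 3 decimals. The simulated time always lies in
#' `[t_min, t_max]`, matching the per-molecule docking-time range the engine's
#' timing histogram is designed around.
#'
#' @param records List of [molecule_record()] objects.
#' @param sleep_factor Real seconds slept per simulated second (default 0,
#'   so tests run instantly while recorded times keep their distribution).
#' @param t_min,t_max Bounds of the simulated per-molecule docking time, in
#'   seconds. Defaults 0.75 and 1.50.
#' @return List of scored records (poses) in input order, one per input.
#' @export
mock_dock <- function(records, sleep_factor = 0, t_min = 0.75, t_max = 1.50) {
  stopifnot(is.list(records), sleep_factor >= 0, t_min >= 0, t_min <= t_max)
  out <- vector("list", length(records))
  total_t <- 0
  for (i in seq_along(records)) {
    rec <- records[[i]]
    score <- mock_score_value(rec$id, heavy_atom_count(rec))
    t <- mock_time_value(rec$id, t_min, t_max)
    total_t <- total_t + t
    rec <- set_tag(rec, "Score", sprintf("%.3f", score))
    rec <- set_tag(rec, "DockingTimeSeconds", sprintf("%.3f", t))
    out[[i]] <- rec
  }
  if (sleep_factor > 0) Sys.sleep(total_t * sleep_factor)
  out
}

#' Receptor specification
#'
#' The receptor is opaque to the engine: a file path plus a scoring-method
#' token and a search-resolution token, all passed through unmodified to the
#' docking backend's command line.
#'
#' @param receptor_path Path to the receptor file.
#' @param scoring_method Scoring-method token (e.g. `"Chemgauss4"`).
#' @param search_resolution Search-resolution token (e.g. `"High"`).
#' @param must_exist Require `receptor_path` to exist (default `TRUE`; set
#'   `FALSE` only when assembling a command for inspection).
#' @return An object of class `receptor_spec`.
#' @export
receptor_spec <- function(receptor_path, scoring_method, search_resolution,
                          must_exist = TRUE) {
  stopifnot(is.character(receptor_path), length(receptor_path) == 1L)
  if (must_exist && !file.exists(receptor_path))
    ds_error("config", sprintf("receptor file not found: %s", receptor_path))
  structure(
    list(receptor_path = receptor_path,
         scoring_method = as.character(scoring_method),
         search_resolution = as.character(search_resolution)),
    class = "receptor_spec"
  )
}

#' Build a backend command from a template
#'
#' Substitutes `{receptor}`, `{scoring_method}` and `{search_resolution}`
#' placeholders into a command template. The template is tokenised first and
#' placeholders are substituted within tokens, so a value containing spaces
#' stays a single argument — substituted values are never shell-interpreted.
#'
#' @param spec A [receptor_spec()].
#' @param template Command template: a single string split on whitespace, or
#'   a character vector of pre-split argument tokens. Each placeholder may
#'   appear at most once.
#' @return Character vector: the argument vector of the backend invocation.
#' @export
make_backend_command <- function(spec, template) {
  stopifnot(inherits(spec, "receptor_spec"), is.character(template))
  tokens <- if (length(template) == 1L)
    strsplit(trimws(template), "[[:space:]]+")[[1]]
  else template
  values <- c(receptor = spec$receptor_path,
              scoring_method = spec$scoring_method,
              search_resolution = spec$search_resolution)
  for (key in names(values)) {
    ph <- paste0("{", key, "}")
    hit <- grepl(ph, tokens, fixed = TRUE)
    if (sum(hit) > 1L)
      ds_error("config", sprintf("placeholder %s appears more than once", ph))
    tokens <- vapply(tokens, function(tk)
      gsub(ph, values[[key]], tk, fixed = TRUE), character(1),
      USE.NAMES = FALSE)
  }
  leftover <- regmatches(tokens, regexpr("\\{[^{}]*\\}", tokens))
  leftover <- leftover[!is.na(leftover) & nzchar(leftover)]
  if (length(leftover))
    ds_error("config", sprintf("unknown placeholder(s) in template: %s",
                               paste(unique(leftover), collapse = ", ")))
  tokens
}

#' Invocation vector for the bundled mock docking executable
#'
#' Returns the argument vector that runs the packaged `mock-dock.R` script —
#' an external process honouring the backend contract (SDF on stdin, scored
#' SDF on stdout) — so the engine's pipe machinery is exercised exactly as it
#' would be with a real docking program.
#'
#' @inheritParams mock_dock
#' @return Character vector: `Rscript` plus the script path and options.
#' @export
mock_backend_command <- function(sleep_factor = 0, t_min = 0.75, t_max = 1.50) {
  script <- system.file("exec", "mock-dock.R", package = "dockscreen")
  if (!nzchar(script)) script <- system.file("inst", "exec", "mock-dock.R",
                                             package = "dockscreen")
  if (!nzchar(script))
    ds_error("config", "bundled mock-dock.R script not found")
  c(file.path(R.home("bin"), "Rscript"), "--vanilla", script,
    "--sleep-factor", format(sleep_factor),
    "--t-min", format(t_min), "--t-max", format(t_max))
}

#' Score and simulated docking time of a pose
#'
#' Accessors for the numeric `Score` and `DockingTimeSeconds` tags a backend
#' writes on each pose.
#'
#' @param pose A scored [molecule_record()].
#' @return A numeric scalar; `pose_score()` errors if the tag is missing or
#'   non-numeric, `pose_time()` returns `NA` if absent.
#' @export
pose_score <- function(pose) {
  v <- get_tag(pose, "Score")
  s <- suppressWarnings(as.numeric(v))
  if (is.na(v) || is.na(s))
    ds_error("data", sprintf("pose %s: missing or non-numeric Score tag",
                             pose$id))
  s
}

#' @rdname pose_score
#' @export
pose_time <- function(pose) {
  suppressWarnings(as.numeric(get_tag(pose, "DockingTimeSeconds")))
}
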