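#' Chunking and parsing configuration
#'
#' Controls how multi-record SDF input is split into molecule records and how
#' molecule identifiers are resolved.
#'
#' @param chunk_size Number of molecules grouped into one unit of work for a
#'   single docking-executable invocation. Larger chunks amortise backend
#'   start-up cost; smaller chunks balance load better. Default 30.
#' @param id_fallback_tag Optional name of a data-item tag to use as the
#'   molecule ID when the title line (line 1 of a record) is blank.
#' @param strict_ids If `TRUE` (default), a record whose title line is blank
#'   and whose fallback tag is absent raises a missing-ID error. If `FALSE`,
#'   an ID of the form `"ANON_<ordinal>"` is synthesised.
#'
#' @return An object of class `chunking_config`.
#' @export
chunking_config <- function(chunk_size = 30L, id_fallback_tag = NULL,
                            strict_ids = TRUE) {
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    ds_error("config", "chunk_size must be a positive integer")
  if (!is.null(id_fallback_tag)) {
    id_fallback_tag <- as.character(id_fallback_tag)
    stopifnot(length(id_fallback_tag) == 1L, nzchar(id_fallback_tag))
  }
  structure(
    list(chunk_size = chunk_size, id_fallback_tag = id_fallback_tag,
         strict_ids = isTRUE(strict_ids)),
    class = "chunking_config"
  )
}

#' Construct a molecule record
#'
#' A molecule record holds one SDF (MDL V2000) entry: its resolved identifier,
#' the connection-table text (everything from the title line through
#' `M  END`), and an ordered named vector of data-item tags.
#'
#' @param id Non-empty molecule identifier.
#' @param ctab Connection-table text, a single string with LF line endings.
#' @param tags Named character vector of data items (may be empty).
#'
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(id, ctab, tags = character(0)) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(ctab), length(ctab) == 1L,
            is.character(tags))
  if (length(tags) && (is.null(names(tags)) || any(!nzchar(names(tags)))))
    ds_error("validation", "all tags must be named")
  structure(list(id = id, ctab = ctab, tags = tags),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record %s: %d ctab lines, %d tags>\n",
              x$id, length(strsplit(x$ctab, "\n", fixed = TRUE)[[1]]),
              length(x$tags)))
  invisible(x)
}

render_tags <- function(tags) {
  if (!length(tags)) return(character(0))
  unlist(lapply(seq_along(tags), function(i) {
    c(paste0("> <", names(tags)[i], ">"),
      strsplit(tags[[i]], "\n", fixed = TRUE)[[1]],
      "")
  }), use.names = FALSE)
}

#' Full text of an SDF record
#'
#' Renders a molecule record back to the text of its SDF entry: the
#' connection table followed by all data items, up to and excluding the
#' `$$$$` terminator line.
#'
#' @param record A [molecule_record()].
#' @return Character vector of lines.
#' @export
record_lines <- function(record) {
  stopifnot(inherits(record, "molecule_record"))
  c(strsplit(record$ctab, "\n", fixed = TRUE)[[1]], render_tags(record$tags))
}

#' @rdname record_lines
#' @return `raw_block()` returns the same text as a single string.
#' @export
raw_block <- function(record) {
  paste(record_lines(record), collapse = "\n")
}

#' Read a tag value from a record
#'
#' @param record A [molecule_record()].
#' @param name Tag name.
#' @return The tag value, or `NA_character_` if absent.
#' @export
get_tag <- function(record, name) {
  stopifnot(inherits(record, "molecule_record"))
  if (name %in% names(record$tags)) unname(record$tags[[name]])
  else NA_character_
}

#' Set or replace a data-item tag on a record
#'
#' Returns a copy of the record whose tags contain `name -> value`, replacing
#' any prior value in place (tag order is otherwise preserved; a new tag is
#' appended). The rendered record embeds the data item before the terminator.
#'
#' @param record A [molecule_record()].
#' @param name Tag name: non-empty, no angle brackets or line breaks.
#' @param value Tag value: single- or multi-line text without blank lines.
#' @return The modified `molecule_record`.
#' @export
set_tag <- function(record, name, value) {
  stopifnot(inherits(record, "molecule_record"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name) ||
      grepl("[<>\n\r]", name))
    ds_error("validation",
             "tag name must be non-empty with no angle brackets or line breaks")
  value <- as.character(value)
  stopifnot(length(value) == 1L)
  vlines <- strsplit(value, "\n", fixed = TRUE)[[1]]
  if (!length(vlines) || any(!nzchar(vlines)))
    ds_error("validation",
             sprintf("value for tag <%s> must not contain blank lines", name))
  record$tags[[name]] <- value
  record
}

grow_list <- function(lst, n_used) {
  if (n_used < length(lst)) return(lst)
  length(lst) <- max(16L, 2L * length(lst))
  lst
}

parse_record_lines <- function(lines, ordinal, config) {
  if (length(lines) < 4L)
    ds_error("format", sprintf(
      "record %d: too short to contain a V2000 counts line", ordinal))
  counts <- lines[4L]
  if (grepl("V3000", counts, fixed = TRUE))
    ds_error("unsupported_dialect", sprintf(
      "record %d: V3000 connection tables are not supported", ordinal))
  natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(natoms) || is.na(nbonds)) {
    toks <- strsplit(trimws(counts), "[[:space:]]+")[[1]]
    natoms <- suppressWarnings(as.integer(toks[1L]))
    nbonds <- suppressWarnings(as.integer(toks[2L]))
  }
  if (is.na(natoms) || is.na(nbonds) || natoms < 0L || nbonds < 0L)
    ds_error("format", sprintf(
      "record %d: malformed counts line: %s", ordinal, dQuote(counts)))

  tag_starts <- grep("^>[[:space:]]*<", lines)
  ctab_end <- if (length(tag_starts)) tag_starts[1L] - 1L else length(lines)
  # drop separator blanks between M  END and the first data item
  while (ctab_end > 4L && !nzchar(trimws(lines[ctab_end]))) {
    ctab_end <- ctab_end - 1L
  }

  tags <- character(0)
  i <- ctab_end + 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^>[[:space:]]*<", lines[i])) {
      m <- regmatches(lines[i], regexpr("<[^<>]*>", lines[i]))[1L]
      name <- substr(m, 2L, nchar(m) - 1L)
      if (!nzchar(name))
        ds_error("format", sprintf(
          "record %d: empty tag name in data-item header", ordinal))
      j <- i + 1L
      vlines <- character(0)
      while (j <= n && nzchar(trimws(lines[j], which = "right")) &&
             !grepl("^>[[:space:]]*<", lines[j])) {
        vlines <- c(vlines, lines[j])
        j <- j + 1L
      }
      tags[[name]] <- paste(vlines, collapse = "\n")
      i <- j
    } else {
      i <- i + 1L
    }
  }

  id <- trimws(lines[1L])
  if (!nzchar(id)) {
    fb <- config$id_fallback_tag
    fbval <- if (!is.null(fb) && fb %in% names(tags)) trimws(tags[[fb]]) else ""
    if (nzchar(fbval)) {
      id <- fbval
    } else if (config$strict_ids) {
      ds_error("missing_id", sprintf(
        "record %d: blank title line and no usable fallback tag%s", ordinal,
        if (is.null(fb)) "" else sprintf(" <%s>", fb)))
    } else {
      id <- sprintf("ANON_%d", ordinal)
    }
  }

  molecule_record(id, paste(lines[seq_len(ctab_end)], collapse = "\n"), tags)
}

#' Parse a multi-record SDF source
#'
#' Record-boundary-aware reader for MDL V2000 SDF: records are delimited by a
#' line equal to `$$$$` after stripping trailing whitespace and carriage
#' returns. Line endings are normalised to LF. The source is consumed in
#' buffered blocks so memory stays bounded by the output plus one block.
#'
#' @param src A file path, a text connection, or a character vector of lines.
#' @param config A [chunking_config()] (controls ID resolution).
#'
#' @return A list of [molecule_record()] objects in source order.
#' @seealso [write_sdf()], [chunk_records()]
#' @export
parse_sdf <- function(src, config = chunking_config()) {
  stopifnot(inherits(config, "chunking_config"))

  from_lines <- is.character(src) &&
    (length(src) != 1L || !file.exists(src))
  if (from_lines) {
    con <- NULL
    pending <- src
  } else if (is.character(src)) {
    con <- file(src, open = "rt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    pending <- NULL
  } else if (inherits(src, "connection")) {
    con <- src
    if (!isOpen(con)) {
      open(con, open = "rt")
      on.exit(close(con), add = TRUE)
    }
    pending <- NULL
  } else {
    ds_error("io", "src must be a file path, connection, or character lines")
  }

  records <- vector("list", 16L)
  nrec <- 0L
  carry <- character(0)
  repeat {
    block <- if (!is.null(pending)) {
      b <- pending; pending <- NULL; b
    } else {
      readLines(con, n = 20000L, warn = FALSE)
    }
    done <- is.null(con) || length(block) == 0L
    lines <- c(carry, sub("\r$", "", block))
    term <- which(trimws(lines, which = "right") == "$$$$")
    start <- 1L
    for (t in term) {
      nrec <- nrec + 1L
      records <- grow_list(records, nrec)
      rec_lines <- if (t > start) lines[start:(t - 1L)] else character(0)
      records[[nrec]] <- parse_record_lines(rec_lines, nrec, config)
      start <- t + 1L
    }
    carry <- if (start <= length(lines)) lines[start:length(lines)] else character(0)
    if (done && length(block) == 0L) break
    if (done) {
      # character-vector input is a single block
      break
    }
  }
  if (any(nzchar(trimws(carry))))
    ds_error("trailing_garbage", sprintf(
      "non-whitespace content after the last \"$$$$\" terminator (%d lines)",
      sum(nzchar(trimws(carry)))))
  length(records) <- nrec
  records
}

#' Write molecule records as multi-record SDF
#'
#' Each record's text is emitted verbatim followed by a `$$$$` terminator
#' line, so `parse_sdf(write_sdf(x))` reproduces `x` exactly.
#'
#' @param records List of [molecule_record()] objects.
#' @param sink A file path or writable text connection.
#' @return Invisibly, the number of records written.
#' @export
write_sdf <- function(records, sink) {
  stopifnot(is.list(records))
  if (is.character(sink)) {
    con <- file(sink, open = "wt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
  } else if (inherits(sink, "connection")) {
    con <- sink
  } else {
    ds_error("io", "sink must be a file path or connection")
  }
  for (rec in records) {
    stopifnot(inherits(rec, "molecule_record"))
    writeLines(c(record_lines(rec), "$$$$"), con)
  }
  invisible(length(records))
}

#' Group records into fixed-size chunks
#'
#' Greedy fill in source order: every chunk except possibly the last holds
#' exactly `chunk_size` records, and concatenating all chunks reproduces the
#' input sequence.
#'
#' @param records List of [molecule_record()] objects.
#' @param chunk_size Positive integer; default 30.
#' @return A list of `sdf_chunk` objects, each with fields `index` (1-based
#'   position in source order) and `records`.
#' @export
chunk_records <- function(records, chunk_size = 30L) {
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    ds_error("config", "chunk_size must be >= 1")
  n <- length(records)
  if (n == 0L) return(list())
  n_chunks <- (n + chunk_size - 1L) %/% chunk_size
  lapply(seq_len(n_chunks), function(i) {
    lo <- (i - 1L) * chunk_size + 1L
    hi <- min(i * chunk_size, n)
    structure(list(index = i, records = records[lo:hi]), class = "sdf_chunk")
  })
}

#' @export
print.sdf_chunk <- function(x, ...) {
  cat(sprintf("<sdf_chunk %d: %d records>\n", x$index, length(x$records)))
  invisible(x)
}
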