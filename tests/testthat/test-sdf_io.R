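test_that("records are split on $$$$ terminators in file order", {
  lib <- tmp_library(3)
  recs <- parse_sdf(lib)
  expect_length(recs, 3)
  expect_equal(vapply(recs, function(r) r$id, character(1)),
               c("MOL000001", "MOL000002", "MOL000003"))
})

test_that("data items are exposed as tags", {
  rec <- make_chain_records(1)[[1]]
  rec <- set_tag(rec, "Score", "12.500")
  lines <- c(record_lines(rec), "$$$$")
  reparsed <- parse_sdf(lines)[[1]]
  expect_identical(get_tag(reparsed, "Score"), "12.500")
  # tag header annotations after the angle-bracket group are tolerated
  annotated <- sub("^> <Score>$", "> <Score> (1)", lines)
  expect_identical(get_tag(parse_sdf(annotated)[[1]], "Score"), "12.500")
})

test_that("CRLF line endings and padded terminators are normalised", {
  lib <- tmp_library(2)
  lines <- readLines(lib)
  crlf <- paste0(sub("^\\$\\$\\$\\$$", "$$$$  ", lines), "\r")
  recs <- parse_sdf(crlf)
  expect_length(recs, 2)
  expect_false(any(grepl("\r", vapply(recs, raw_block, character(1)))))
})

test_that("malformed input raises typed errors", {
  lines <- readLines(tmp_library(1))
  # text after the final terminator
  expect_error(parse_sdf(c(lines, "leftover")),
               class = "dockscreen_trailing_garbage_error")
  # record not terminated at all
  expect_error(parse_sdf(lines[-length(lines)]),
               class = "dockscreen_trailing_garbage_error")
  # V3000 dialect
  v3 <- lines
  v3[4] <- sub("V2000", "V3000", v3[4])
  expect_error(parse_sdf(v3), class = "dockscreen_unsupported_dialect_error")
  # garbage counts line, error names the record ordinal
  bad <- lines
  bad[4] <- "not a counts line"
  expect_error(parse_sdf(bad), regexp = "record 1",
               class = "dockscreen_format_error")
})

test_that("blank titles follow the strict/fallback/lenient ID policy", {
  rec <- make_chain_records(1)[[1]]
  rec <- set_tag(rec, "zinc_id", "ZINC0042")
  lines <- c(record_lines(rec), "$$$$")
  lines[1] <- ""
  expect_error(parse_sdf(lines), class = "dockscreen_missing_id_error")
  with_fb <- parse_sdf(lines, chunking_config(id_fallback_tag = "zinc_id"))
  expect_identical(with_fb[[1]]$id, "ZINC0042")
  lenient <- parse_sdf(lines, chunking_config(strict_ids = FALSE))
  expect_identical(lenient[[1]]$id, "ANON_1")
})

test_that("write/parse round trip is the identity, and terminators count out", {
  recs <- make_chain_records(10)
  recs[[4]] <- set_tag(recs[[4]], "Note", "two\nlines")
  path <- tempfile(fileext = ".sdf")
  expect_identical(write_sdf(recs, path), 10L)
  back <- parse_sdf(path)
  expect_identical(lapply(back, unclass), lapply(recs, unclass))

  path100 <- tmp_library(100)
  expect_identical(sum(readLines(path100) == "$$$$"), 100L)
  expect_length(parse_sdf(path100), 100)
})

test_that("writing an empty sequence yields an empty file", {
  path <- tempfile(fileext = ".sdf")
  expect_identical(write_sdf(list(), path), 0L)
  expect_identical(file.size(path), 0)
  expect_length(parse_sdf(path), 0)
})

test_that("chunking fills greedily and conserves records", {
  recs <- make_chain_records(100)
  chunks <- chunk_records(recs, 30)
  expect_equal(vapply(chunks, function(ch) length(ch$records), integer(1)),
               c(30L, 30L, 30L, 10L))
  expect_equal(vapply(chunks, function(ch) ch$index, integer(1)), 1:4)
  # order preservation after unchunking
  flat <- do.call(c, lapply(chunks, function(ch) ch$records))
  expect_identical(lapply(flat, unclass), lapply(recs, unclass))

  expect_length(chunk_records(list(), 30), 0)
  expect_error(chunk_records(recs, 0), class = "dockscreen_config_error")
  # default chunk size is 30
  expect_identical(chunking_config()$chunk_size, 30L)
  expect_identical(formals(chunk_records)$chunk_size, 30L)
})

test_that("every chunk element re-parses as a valid record", {
  recs <- make_chain_records(23)
  for (ch in chunk_records(recs, 7)) {
    for (r in ch$records) {
      rt <- parse_sdf(c(record_lines(r), "$$$$"))
      expect_identical(unclass(rt[[1]]), unclass(r))
    }
  }
})

test_that("set_tag replaces in place and survives a round trip", {
  rec <- make_chain_records(1)[[1]]
  r1 <- set_tag(rec, "Score", "7.250")
  expect_identical(unname(r1$tags), "7.250")
  r2 <- set_tag(set_tag(rec, "Score", "1.000"), "Score", "2.000")
  expect_identical(get_tag(r2, "Score"), "2.000")
  expect_identical(sum(grepl("^> <Score>$", record_lines(r2))), 1L)

  path <- tempfile(fileext = ".sdf")
  write_sdf(list(r2), path)
  expect_identical(get_tag(parse_sdf(path)[[1]], "Score"), "2.000")

  expect_error(set_tag(rec, "bad<name>", "x"),
               class = "dockscreen_validation_error")
  expect_error(set_tag(rec, "Note", "a\n\nb"),
               class = "dockscreen_validation_error")
})
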