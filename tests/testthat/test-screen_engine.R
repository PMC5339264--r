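test_that("pipe_chunk through an identity program reproduces the input", {
  chunk <- chunk_records(make_chain_records(2), 30)[[1]]
  res <- pipe_chunk(chunk, "cat")
  expect_s3_class(res, "chunk_result")
  expect_identical(res$attempts, 1L)
  expect_identical(vapply(res$poses, raw_block, character(1)),
                   vapply(chunk$records, raw_block, character(1)))
})

test_that("pipe_chunk through the mock backend scores every molecule", {
  chunk <- chunk_records(make_chain_records(5), 30)[[1]]
  res <- pipe_chunk(chunk, mock_backend_command())
  expect_length(res$poses, 5)
  expect_true(all(vapply(res$poses, function(p)
    !is.na(get_tag(p, "Score")), logical(1))))
  expect_identical(vapply(res$poses, function(p) p$id, character(1)),
                   vapply(chunk$records, function(r) r$id, character(1)))
  expect_gte(res$elapsed, 0)
})

test_that("a persistently failing backend is retried exactly retries+1 times", {
  chunk <- chunk_records(make_chain_records(1), 30)[[1]]
  err <- tryCatch(
    suppressMessages(pipe_chunk(chunk, failing_backend(), retries = 2L)),
    dockscreen_chunk_failure = function(e) e)
  expect_s3_class(err, "dockscreen_chunk_failure")
  expect_identical(err$attempts, 3L)
  expect_identical(err$chunk_index, 1L)
})

test_that("checkpoint splits contiguously and refuses to overwrite", {
  poses <- mock_dock(make_chain_records(10))
  dir <- tempfile()
  parts <- checkpoint(poses, dir, partitions = 2)
  expect_identical(basename(parts), c("part-00000.sdf", "part-00001.sdf"))
  expect_length(parse_sdf(parts[1]), 5)
  expect_length(parse_sdf(parts[2]), 5)
  expect_true(file.exists(file.path(dir, "_SUCCESS")))
  expect_identical(file.size(file.path(dir, "_SUCCESS")), 0)
  expect_error(checkpoint(poses, dir, 2), class = "dockscreen_io_error")

  # re-reading all parts in name order reproduces the sequence
  p100 <- mock_dock(make_chain_records(100))
  d100 <- tempfile()
  checkpoint(p100, d100, partitions = 7)
  expect_identical(lapply(read_checkpoint(d100), unclass),
                   lapply(p100, unclass))

  # zero poses: _SUCCESS only
  d0 <- tempfile()
  expect_length(checkpoint(list(), d0), 0)
  expect_identical(list.files(d0), "_SUCCESS")
})

test_that("share_file is idempotent and validates existence", {
  f <- tempfile()
  writeLines("receptor bytes", f)
  h1 <- share_file(f)
  h2 <- share_file(f)
  expect_identical(h1, h2)
  expect_true(h1 %in% shared_files())
  expect_identical(readLines(h1), "receptor bytes")
  expect_error(share_file(tempfile("missing")),
               class = "dockscreen_config_error")
})

test_that("run_screen dispatches all chunks and manifests them", {
  lib <- tmp_library(100)
  dir <- tempfile()
  run <- suppressMessages(run_screen(
    lib, mock_backend_command(),
    pipeline_config(parallelism = 2, chunk_size = 30,
                    checkpoint_dir = file.path(dir, "checkpoint"))))
  expect_identical(nrow(run$manifest), 4L)
  expect_identical(run$manifest$n_records, c(30L, 30L, 30L, 10L))
  expect_true(all(run$manifest$status == "ok"))
  expect_true(all(run$manifest$attempts == 1L))
  expect_length(run$poses, 100)
  # checkpoint in chunk-index order equals pose order
  expect_identical(lapply(read_checkpoint(run$checkpoint_dir), unclass),
                   lapply(run$poses, unclass))
})

test_that("an empty library screens to an empty, successful checkpoint", {
  lib <- tempfile(fileext = ".sdf")
  file.create(lib)
  dir <- tempfile()
  run <- suppressMessages(run_screen(
    lib, mock_backend_command(),
    pipeline_config(checkpoint_dir = file.path(dir, "ck"))))
  expect_identical(nrow(run$manifest), 0L)
  expect_length(run$poses, 0)
  expect_true(file.exists(file.path(dir, "ck", "_SUCCESS")))
})

test_that("the pose multiset is invariant to the parallelism level", {
  recs <- make_chain_records(60)
  runs <- lapply(c(1L, 2L, 4L), function(p) {
    run <- suppressMessages(run_screen(
      recs, mock_backend_command(),
      pipeline_config(parallelism = p, chunk_size = 20,
                      checkpoint_dir = tempfile())))
    poses <- run$poses
    ids <- vapply(poses, function(x) x$id, character(1))
    lapply(poses[order(ids, method = "radix")], unclass)
  })
  expect_identical(runs[[1]], runs[[2]])
  expect_identical(runs[[1]], runs[[3]])
})

test_that("failure policies escalate as configured", {
  recs <- make_chain_records(4)
  bad <- failing_backend()
  dir1 <- tempfile()
  expect_error(
    suppressMessages(run_screen(
      recs, bad,
      pipeline_config(chunk_size = 2, retries = 0L,
                      on_failure = "fail_fast",
                      checkpoint_dir = file.path(dir1, "ck")))),
    class = "dockscreen_run_failure")
  # partial checkpoint preserved even on abort
  expect_true(file.exists(file.path(dir1, "ck", "_SUCCESS")))

  dir2 <- tempfile()
  run <- suppressMessages(run_screen(
    recs, bad,
    pipeline_config(chunk_size = 2, retries = 0L,
                    on_failure = "quarantine",
                    checkpoint_dir = file.path(dir2, "ck"))))
  expect_true(all(run$manifest$status == "failed"))
  expect_true(file.exists(run$quarantine))
  expect_length(parse_sdf(run$quarantine), 4)
  expect_length(run$poses, 0)
})
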