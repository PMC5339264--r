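# Synthetic SDF library generator. Molecules are linear carbon chains —
# deliberately toy chemistry: the pipeline exercises format handling,
# chunking and scoring plumbing, not molecular realism. Chain lengths cycle
# 1..max_chain_length so heavy-atom counts (and hence mock scores) are
# analytically predictable from the molecule index.

make_chain_record <- function(i, max_chain_length = 20L, id_prefix = "MOL") {
  k <- 1L + (i - 1L) %% max_chain_length
  id <- sprintf("%s%06d", id_prefix, i)
  atoms <- vapply(seq_len(k), function(j) sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    (j - 1L) * 1.5, 0, 0, "C"), character(1))
  bonds <- if (k > 1L) vapply(seq_len(k - 1L), function(j)
    sprintf("%3d%3d%3d%3d%3d%3d%3d", j, j + 1L, 1L, 0L, 0L, 0L, 0L),
    character(1)) else character(0)
  ctab <- c(
    id,
    "  dockscreen",
    "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", k, k - 1L),
    atoms,
    bonds,
    "M  END"
  )
  molecule_record(id, paste(ctab, collapse = "\n"))
}

#' Generate a synthetic molecule library in memory
#'
#' Molecule `i` (1-based) is a linear chain of `1 + ((i-1) mod
#' max_chain_length)` carbon atoms spaced 1.5 Å along the x-axis with single
#' bonds and no hydrogens; its title line is `id_prefix` plus the
#' zero-padded 6-digit index. Output is fully determined by the arguments.
#'
#' @param n_molecules Number of records to generate (>= 1 for a library).
#' @param max_chain_length Longest chain before lengths cycle (default 20).
#' @param id_prefix Identifier prefix (default `"MOL"`).
#' @return List of [molecule_record()] objects.
#' @export
make_chain_records <- function(n_molecules, max_chain_length = 20L,
                               id_prefix = "MOL") {
  n_molecules <- as.integer(n_molecules)
  max_chain_length <- as.integer(max_chain_length)
  if (is.na(n_molecules) || n_molecules < 0L)
    ds_error("config", "n_molecules must be a non-negative integer")
  if (is.na(max_chain_length) || max_chain_length < 1L)
    ds_error("config", "max_chain_length must be >= 1")
  lapply(seq_len(n_molecules), make_chain_record,
         max_chain_length = max_chain_length, id_prefix = id_prefix)
}

#' Write a synthetic SDF library
#'
#' Writes `n_molecules` V2000 records built by [make_chain_records()] to
#' `sink`. Identical arguments produce byte-identical files.
#'
#' @inheritParams make_chain_records
#' @param sink File path or writable text connection.
#' @return The number of records written.
#' @export
generate_library <- function(n_molecules, sink, max_chain_length = 20L,
                             id_prefix = "MOL") {
  if (n_molecules < 1L)
    ds_error("config", "a library must contain at least one molecule")
  recs <- make_chain_records(n_molecules, max_chain_length, id_prefix)
  write_sdf(recs, sink)
  n_molecules
}

#' Draw a seeded uniform sample of molecules
#'
#' Samples `k` records without replacement with a seeded generator; the same
#' seed always yields the same sample, source order is preserved within the
#' sample, and the caller's random-number state is left untouched.
#'
#' @param library SDF path or list of [molecule_record()] objects.
#' @param k Sample size (0 <= k <= library size).
#' @param seed Integer seed.
#' @return List of sampled [molecule_record()] objects.
#' @export
sample_molecules <- function(library, k, seed) {
  records <- if (is.character(library) && length(library) == 1L)
    parse_sdf(library) else library
  k <- as.integer(k)
  n <- length(records)
  if (is.na(k) || k < 0L || k > n)
    ds_error("domain", sprintf(
      "sample size %d out of range for library of %d", k, n))
  if (k == 0L) return(list())
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  idx <- sort(sample.int(n, k))
  records[idx]
}
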