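---
title: "A chunked, pipe-based engine for docking virtual screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chunked, pipe-based engine for docking virtual screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockscreen)
```

## The problem and the design

Structure-based virtual screening docks every molecule of a library against
a target receptor and keeps the highest-scoring poses. Three properties of
the workload shape this engine:

1. **Records are multi-line.** An SDF entry spans dozens of lines and ends
   with `$$$$`; a line-oriented splitter would shred records, so the reader
   is record-boundary aware and only ever cuts at terminators.
2. **Docking is slow per record but the program is slow to start.** Feeding
   one molecule per process invocation wastes start-up time; feeding too
   many harms load balance. Chunking is therefore explicit, with a
   `chunk_size` default of 30 molecules per backend invocation — enough to
   amortise start-up, small enough that slots stay busy.
3. **Poses are bulky, scores are tiny.** Ranking is done on (ID, score)
   pairs sorted serially in memory; full poses are retrieved afterwards by
   ID from the checkpoint with a scan-and-filter pass. No full SDF block is
   ever sorted or shuffled.

The execution core (`run_screen()`) maps chunks over `parallelism` worker
slots (forked processes, dynamic greedy assignment: a slot takes the next
pending chunk when free). Assignment order therefore differs run to run,
but results are assembled in chunk-index order, so checkpoints are
reproducible regardless of completion order, and the pose multiset is
invariant to the parallelism level — the property `validate_equivalence()`
checks by screening a seeded sample serially and in parallel and comparing
ID-sorted poses field by field (timing annotations excluded, as they are
the one legitimately run-dependent field).

## The backend contract

A docking backend is any executable that reads multi-record SDF on standard
input until end-of-input, writes one scored SDF record per input molecule
(tag `Score`, higher is better) to standard output in input order, exits 0
on success, and keeps diagnostics on standard error. The engine invokes one
process per chunk — the simplest contract consistent with stream-based
exchange; a persistent server process per slot would amortise start-up
further but complicates failure recovery, and at 30 molecules per
invocation start-up is already a small fraction of chunk time.

Failures (nonzero exit, unparseable output, timeout) are retried per chunk
(`retries`, default 2). Exhausted chunks escalate per `on_failure`:
`fail_fast` aborts the run but preserves the checkpoint of completed work;
`quarantine` writes the failed chunks' input molecules to `quarantine.sdf`
and lets the run complete. The default per-chunk timeout is none, because
docking time is unbounded in general.

Real docking programs are integrated purely by configuration:
`make_backend_command()` substitutes `{receptor}`, `{scoring_method}` and
`{search_resolution}` into a command template token-wise, so substituted
values are never shell-interpreted and a value containing spaces remains a
single argument.

## The mock backend

The bundled mock backend makes the full pipeline testable with no docking
software. For a molecule with ID string $s$ and heavy-atom count $H$:

$$\mathrm{score} = H + \frac{\mathrm{CRC32}(s) \bmod 1000}{1000},
\qquad
t = t_{\min} + \frac{\mathrm{CRC32}(s) \bmod 1001}{1000}\,(t_{\max}-t_{\min})$$

with $t_{\min} = 0.75$ s and $t_{\max} = 1.50$ s, the range typical of a
per-molecule docking call and the range the timing histogram is designed
around. Both values are written as tags (`Score`, `DockingTimeSeconds`)
with three decimals. CRC-32 (IEEE polynomial) was chosen as the hash
because it is exactly specified, ubiquitous, and independent of any
language runtime's string-hash randomisation, so scores are reproducible
across machines and parallelism levels; the package carries its own
table-driven implementation (verified against zlib) because base R exposes
no CRC-32. `sleep_factor` (default 0) optionally converts simulated seconds
into real sleeping, so tests run instantly while the recorded times still
have a realistic spread.

What the mock does *not* emulate: real score distributions (scores here
grow with molecule size by construction), docking failures of individual
molecules (output is always 1:1 with input), pose geometry, and heavy-tailed
docking times. Passing tests therefore demonstrate the correctness of the
*plumbing* — chunking, piping, retries, checkpointing, ranking — not
chemistry.

## Synthetic libraries

`generate_library(n)` writes molecule $i$ as a linear chain of
$1 + ((i-1) \bmod 20)$ carbon atoms, 1.5 Å apart on the x-axis, single
bonds, no hydrogens, titled `MOL` + zero-padded index. Toy chemistry is
deliberate: heavy-atom counts cycle predictably, so expected mock scores
are analytic in the index, and generation is fully determined by its
arguments — which is why, although sampling (`sample_molecules()`) is
seeded, generation takes no seed: there is no randomness left for one to
control. Generated files are valid V2000 (cross-checked in the test suite
with an independent cheminformatics parser; note that single-atom records
have an empty bond block, which some validators flag despite being legal).

## Metrics

*Weak scaling efficiency* is $T(1\ \mathrm{PE}, 1\ \mathrm{WU}) /
T(N\ \mathrm{PE}, N\ \mathrm{WU})$; 1 is perfect, superlinear values are
allowed. *Speedup* is $T_1 / T_N$ with $T_1$ the sum of per-pose annotated
times — the reason every pose carries `DockingTimeSeconds`. Percentages are
rendered by rounding half away from zero, matching how such figures are
quoted.

`estimate_wse_from_aggregates()` recovers WSE when a benchmark publishes
only totals: with $n$ molecules at parallelism $p$, total serial time $T_s$
and parallel wall time $T_p$, the work unit is $\mathrm{round}(n/p)$
molecules, the per-molecule time $\mathrm{round}(T_s/n)$ seconds (both
half-away-from-zero, integer — mirroring how aggregate figures are printed,
so the worked example is exact), the work-unit time their product, and WSE
that product over $T_p$. Unrounded intermediates are retained. The standard
worked example:

```{r}
estimate_wse_from_aggregates(n_molecules = 2637, parallelism = 570,
                             total_serial_time = 69 * 3600,
                             parallel_time = 550)
```

`time_histogram()` uses equally spaced bins spanning the data range
(default 20 bins), left-closed with the last bin closed on both sides, so
counts always conserve the observation total. When all observations are
identical the zero-width range is widened by ±0.5 around the value so the
single occupied bin is well defined. The histogram spans the observed range
rather than a fixed interval, since timing ranges are backend-specific.

## Numerical and degenerate-input choices

- **Ties in top-N** are broken by ascending ID in byte (C-locale radix)
  order, so rankings are deterministic and locale-independent. Duplicate
  IDs keep the higher-scoring pose, with a warning — libraries are expected
  to have unique IDs.
- **ID resolution**: the title line; if blank, a configurable fallback tag;
  strict mode (default) errors, lenient mode synthesises `ANON_<ordinal>`.
  Strict is the default because hit retrieval is by ID and a silent
  synthetic ID could mask a malformed library.
- **Dialects**: V2000 only; a V3000 marker raises a typed error. `$$$$` is
  recognised after stripping trailing whitespace/CR, and CRLF input is
  normalised to LF, because real libraries mix line endings. Tag names are
  taken from the first angle-bracket group of the data-item header,
  tolerating trailing annotations.
- **Checkpoint layout**: `part-00000.sdf`, ..., contiguous in-order split,
  `_SUCCESS` written last; a non-empty target directory is refused rather
  than overwritten. The part-file convention matches distributed text-save
  output so checkpoints interoperate with that ecosystem.
- **Empty inputs**: an empty library screens to an empty checkpoint with
  `_SUCCESS` (success, not error); an empty ID list retrieves no poses.

## Problem sizes in the test suite

The suite exercises end-to-end equivalence at 1000 molecules (parallelism
1 vs 4, chunk size 100 — equivalence is chunk-size-invariant, and 100 keeps
process launches to ten per run), the top-N oracle on 200 random score
lists, chunk-conservation across library sizes 0–1000, and timing bounds on
10 000 simulated times. These sizes give full coverage of the contracts at
interactive runtimes; the engine itself has no scale-dependent branches, so
behaviour at millions of molecules differs only in wall time and in the
load-balancing quality of the greedy scheduler.

## Known limitations

- Single-machine parallelism (forked processes); no distributed scheduling,
  locality, or speculative execution.
- The engine buffers each chunk's input before handing it to the child
  process; the *backend* sees pure streams, but the engine side is not a
  fully streaming bidirectional pipe.
- Scores are taken as-is; no normalisation or rescoring.
- A backend that legitimately drops molecules is only supported with
  `allow_partial = TRUE` on `pipe_chunk()`; the default treats 1:1 output
  as part of the contract.
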