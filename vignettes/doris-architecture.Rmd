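---
title: "Overhang-addressed DNA storage: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overhang-addressed DNA storage: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dorisim)
```

## The system being modelled

`dorisim` models a DNA information-storage architecture whose unit is the
ss-dsDNA strand: a mostly double-stranded molecule whose 3'-terminal 20 nt
remain single stranded. That overhang is the *file address* — every strand of
one file shares it — and it is the handle for everything dynamic in the
system: magnetic-bead separation with a complementary biotinylated oligo,
and toehold-mediated file operations (lock, unlock, rename, delete). A fixed
23 nt region immediately 5' of the address carries the T7 promoter and the
binding site of a single common primer, so a pool of synthesized ssDNA
templates converts to ss-dsDNA in one pot, and files are *read* by T7 in
vitro transcription (IVT) rather than destroyed by removal: transcripts go
to RT-PCR and sequencing while the strands return to the database.

Templates are kept as plain 5'→3' character strings; coordinates are 0-based
and half-open, from the 5' end. Primer-site matching in `build_ssdsdna()` is
exact (the common primer is designed perfectly complementary to its site);
mismatch-tolerant annealing is deliberately out of scope. After fill-in the
duplex is taken to cover everything 5' of the address — the polymerase runs
to the template end, so the two pad bases between the 21 nt primer site and
the 23 nt region boundary end up double stranded too.

The printed primer is `r doris_primer()`. The reference geometry is
checked directly: a 160 nt template leaves a 20 nt overhang, and the 50 nt
lock, paired over those 20 nt, presents a 30 nt toehold.

The 23 nt promoter-region *sequence* is not published; the package default
(`default_promoter_region()`) is the reverse complement of the common primer
padded with two leading `G`s, which satisfies the one-exact-primer-site
precondition by construction. Nothing downstream depends on the identity of
those 23 bases, only on their length and position.

## Codec, density, capacity

Bytes map to fixed-length codewords (L nt each, one byte per codeword). A
strand's payload region (160 nt by default) holds `floor(160 / L)`
codewords, the first 5 of which encode the strand's ordinal index in
big-endian base 256 — 256^5 ordinals comfortably index the 1e9 strands a
file is assumed to hold. Hence the analytic models:

* density `(160 − 5 L) / L` bytes per strand (35 B at L = 4, 100/12 ≈ 8.3 B
  at L = 12),
* capacity `1e9 × n_addresses × density / 10` bytes, with 1e9 strands per
  file (about one sequencing run) and 10 physical replicates per strand.

Design choices the byte↔DNA mapping needed but the source material leaves
open: the codeword table is the first 256 L-mers in lexicographic order
after applying any homopolymer constraint (forced to all 256 4-mers at
L = 4); a seeded uniformly-sampled table is available (`method = "random"`)
where junction diversity closer to arbitrary encodings is wanted; the final
partial strand is padded with byte-0 codewords and the true payload length
travels in a manifest, because trailing zeros are otherwise ambiguous. No
error-correcting code is layered on: the conflict questions studied here
concern addresses, not channel noise.

## Address design and the Monte Carlo survey

Addresses must be mutually orthogonal; the screening criterion is Hamming
distance, with "similar" meaning distance < 6. `mutual_orthogonality_filter()`
is greedy accept-in-order (order = candidate generation order under the
run's seed, for determinism) and screens each candidate against accepted
addresses *and their reverse complements*, since an oligo can meet either
strand of a melted duplex. Candidates are uniform random 20-mers filtered to
GC 0.40–0.60 and homopolymer runs ≤ 3 — standard primer heuristics standing
in for unpublished search criteria, and configurable.

The survey contrasts two access chemistries over the same candidates:

* **PCR mode** melts the duplex every cycle, so an address must also avoid
  every 20 nt window of every payload (either orientation, distance < 6 is
  a conflict).
* **Overhang (DORIS) mode** never melts the payload, so only mutual
  orthogonality applies — the survivor count is invariant to the database
  and to L, which is the architecture's defining advantage: capacity then
  rises monotonically as codewords shrink.

Scanning ~1e4 candidates against every window of 1e4 sampled strands is the
hot loop; it runs as 2-bit-packed XOR/popcount comparisons in C++ with the
window set deduplicated (codeword-built payloads repeat windows heavily)
and early exit per candidate. Payload conflicts are assessed against a
random sample of database strands (default 1e4) because exhaustive checking
of realistic databases is intractable; at the survey's own desk scale —
1e4 candidates versus a 1e5-strand synthetic database per codeword length —
the sample is usually the whole database of interest. The full-enumeration
path (`payload_sample = Inf`) exists and is tested against a brute-force
oracle. Desk scale keeps the whole two-mode, five-length survey inside a
couple of minutes on one CPU; the published-scale survey (4e5 candidates,
1e9-strand extrapolation) is reachable through the same configuration knobs
but is not a test target.

## Thermodynamic capture model

Oligo–overhang binding is treated as a two-state equilibrium,
`K = exp(−ΔG°/RT)` with R = 1.987e−3 kcal/(mol·K). The bound:free ratio
`K·[oligo]` is reported two ways: clipped at 1 (`literal_clipped`,
the default, the literal reading of the equilibrium algebra) and as the standard saturating isotherm
`K·[oligo]/(1 + K·[oligo])`. They agree to first order whenever
`K·[oligo] ≪ 1`; the saturating form is the thermodynamically bounded one.
ΔG° comes from a unified nearest-neighbor DNA/DNA parameter set (1 M NaCl;
pluggable table) — the ΔG° values behind the reference separation data came from a web
calculator and were never tabulated, so a published parameterization
stands in. Salt
correction, dangling ends, and mismatches are out of scope. The model
reproduces the qualitative separation trends: longer oligos bind more, and
binding weakens with temperature.

## The lifecycle simulator

All stochastic steps are binomial (or Poisson, for transcript counts) on
integer copy counts under one seed, so copies move rather than duplicate:
`retained + bound` equals the pre-separation database exactly.

Capture is exact-match on the exposed overhang with one probability
parameter (default 0.5, the observed room-temperature separation level);
mechanistic temperature/length dependence can be layered on from the thermo
module but is not the default, because the empirical quantity available for
calibration is the net separation fraction, not rate constants. The state
machine enforces: `LOCKED` and `BLOCKED` strands are never captured below
the lock-melt temperature (45 °C); above it a lock melts off and capture
resumes; `RENAMED` strands answer only to the new address's oligo. PCR-mode
separation ignores state (everything melts) and additionally primes internal
payload sites, emitting truncated-product records with the truncation
coordinate.

Locking fidelity is a two-level model: complete at ≥ 45 °C, leaky below
(default leak fraction 0.05 — the observed cold-locking leak is qualitative,
so the fraction is configurable). Unlocking succeeds at any temperature from
25 °C up, reflecting toehold-mediated displacement through the lock's 30 nt
toehold. The rename oligo is `[new address][complement of old address]`
(40 nt); the delete oligo is the bare 20 nt complement. Operations assume
the printed reagent excesses (`molar_ratios()`: file:lock:key:oligo =
1:10:10:15; file:rename oligo:oligo = 1:10:15) and run to completion up to
the modelled leak.

One access cycle is separate → IVT → return. The calibration constant is
the per-cycle retention of an accessed file, 0.87 per cycle — the fifth root
of the observed ~50% remaining after five accesses. Uncaptured copies stay
put, so captured copies must survive IVT and elution with probability
`s = 1 − (1 − 0.87)/0.5 = 0.74`; by default all of that loss is charged to
the bead-bound IVT stage as a per-hour rate over 8 h (bead unbinding and
degradation are not separable in the available data and are lumped), with
elution left at 1. Each parameter is overridable when the split matters.
The compounded five-access survival 0.87^5 ≈ 0.498 is verified by Monte
Carlo (1000 replicate trajectories of a 200-copy file — small enough to run
in seconds, large enough that the standard error of the mean is ~0.1%). The
database-sizing rule `min_initial_copies()` rounds that compound survival to
the two figures at which it is empirically known (~50%) before taking
`ceiling(1/s)`, giving the budget of 2 initial copies per 5 accesses; at
three-digit precision the same arithmetic would say 3, which overstates the
precision of the measurement it is based on.

The 45 °C reanneal-recovery effect on retention is logged vocabulary only,
not modelled.

## Promoter-variant pool and synthetic reads

The pool enumerates every 5-mer immediately upstream of the promoter (in
the overhang, 1024 strands) and every 3-mer immediately downstream (payload
side, 64 strands): 1088 distinct 160 nt templates on one fixed, seeded
scaffold. Each template carries a barcode at the payload start. The exact
barcodes and their position are unpublished; the package uses 10 nt barcodes
packed greedily to pairwise Hamming distance ≥ 3, so the ≤ 1-mismatch
assignment rule decodes any single read error uniquely. (A distance-2 code —
the minimum that merely keeps barcodes distinct under one error — turns out
to make almost every single substitution ambiguous once all 1088 barcodes
are in play, which is why the stronger code is used; ambiguous reads go to
the unassigned bin rather than to a best guess.)

Synthetic reads are drawn multinomially, weights ∝ abundance (library
sample) or abundance × relative transcription efficiency (post-IVT sample),
with per-base substitution/insertion/deletion errors injected at stated
rates. This emulates the *composition* of an amplicon sequencing run — it
has no quality-score model, no adapter chemistry, no GC or position bias —
so passing tests show the analysis pipeline recovers what the generator put
in, not that real NGS artefacts are handled.

Readout analyses: normalized abundance is the per-variant post/pre count
ratio (undefined, not zero, where pre = 0); quartile position-frequency
matrices rank variants by abundance (ascending, ties broken by sequence so
the split is deterministic) and emit per-quartile base-frequency columns
(logo-renderer input — graphical rendering is out of scope); A/T-content
groups are compared by one-way ANOVA with Tukey–Kramer pairwise
comparisons, dropping degenerate (< 2 member) buckets. Per-position error
rates come from global unit-cost edit-distance alignment of each read to its
assigned reference, with a deterministic tie-break (diagonal over deletion
over insertion, i.e. reference-leftmost indels) since the rate definition
names no aligner; insertions are charged to the following reference
position. Position-level indel attribution inside homopolymer runs is
inherently ambiguous under any minimum-edit criterion, so parameter-recovery
checks compare substitutions per position but indels in aggregate and in
10 nt windows. Error profiling in validation studies can bypass barcode
demultiplexing (`assignment =`), because demultiplexing excludes reads with
corrupted barcodes and would deflate apparent rates at the barcode locus.

## Scales, seeds, determinism

Every stochastic entry point takes a seed; multi-stage pipelines derive
labelled sub-seeds (`derive_seed()`) from one master seed, so any run
replays bit-identically. Test-suite problem sizes are chosen so the whole
suite runs in minutes on one CPU: the survey at 1e4 × 1e5 (the desk scale
above), the retention calibration at 1000 × 200 copies, read analyses at
1e4 reads. The command-line interface (`inst/cli/dorisim.R`) is a thin
wrapper over the exported functions and shares their determinism.

## Known limitations

* Capture is all-or-nothing on exact overhang complementarity; partial
  hybridization and bead-capacity saturation are not modelled.
* Strand-displacement is thermodynamic/endpoint, not kinetic.
* IVT loss lumps bead unbinding and degradation into one rate.
* The synthetic read model omits sequencing-chemistry artefacts, so
  measured wet-lab abundance distributions are calibration inputs, not
  reproducible outputs, at this package's scale.
* Secondary structure (templates, locks at low temperature) is out of
  scope; the cold-locking leak fraction is a stand-in for it.
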