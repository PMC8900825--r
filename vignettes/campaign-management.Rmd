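---
title: "Managing crystallographic fragment-screening campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing crystallographic fragment-screening campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragcampaign)
```

## The problem

A crystallographic fragment screen soaks several hundred protein crystals,
each with one member of a small-molecule fragment library, harvests the
crystals into pucks for the synchrotron sample changer, and counts how many
datasets show a bound fragment. The chemistry and the diffraction happen
elsewhere; what this package implements is everything between — the
addressing, planning, record-keeping and statistics that make a campaign
reproducible from its files. This vignette explains the models and
conventions behind each part, the parameters that matter, and what the
synthetic-data generator does and does not emulate.

## Plate geometry and addressing

Crystals grow in 96-well sitting-drop plates with three subwell drops per
well; an address is row letter, column number, drop letter (`"B7c"`).
Library plates are 384-well (rows A–P) or 1536-well; for 1536 we name rows
A–Z then AA–AF, Excel style, since vendors disagree and the double-letter
convention is the one every spreadsheet user can read. Drop letters are
lower-case in the canonical form and parsing is case-insensitive, so
hand-typed station files round-trip. All indices are 0-based internally
and 1-based in display strings; every parser rejects out-of-range
components by name (row, column or drop) rather than with a generic error.

Geometry lives in `inst/config/plate_geometry.yaml` — rows, columns, drops,
the drop-well half-extent, the per-drop centre offsets, the 2.5 nL droplet
quantum and the 16-pin puck capacity — so another plate type or instrument
is a config change, not a code change.

## Fragment libraries and diversity selection

Libraries arrive as SDF with the catalogue code and source well as data
fields. SMILES are taken from a SMILES field when present, otherwise
derived from the connection table, and always canonicalized at ingest:
`lookup_smiles()` must return the same string on every run because
downstream restraint generation is keyed on it. Duplicate catalogue codes
and shared source wells are rejected at ingest — a picklist with an
ambiguous source well is a wasted plate.

`select_diverse()` implements greedy MaxMin selection: start somewhere, then
repeatedly add the fragment whose minimum Tanimoto distance to the selected
set is largest. Design choices, all made for determinism:

* **Fingerprint**: a 1024-bit path-based binary fingerprint over the
  molecular graph. Descriptor families differ in detail but not in the
  quality of a MaxMin subset; the fingerprint kind is behind
  `fragment_fingerprints()` and can be swapped without touching the
  selection.
* **Initialization**: `seed = 0` starts from the lexicographically smallest
  fragment id (fully deterministic with no RNG state); any other seed picks
  the start uniformly under that seed.
* **Ties** in the minimum distance are broken by fragment id order.

Greedy growth means the selection for `n = k` is a prefix of the selection
for `n = k + 1` — useful when a screen is extended — and the first two picks
equal the brute-force most-distant pair whenever the start is a member of
that pair, which the test suite verifies by enumeration on small sets.

## The campaign store and state machine

Campaign metadata goes into an embedded JSON-lines document store: one file
per account, one document per line, tagged with its collection. The store
is schema-less except for per-collection validators: `Plates` requires
`{barcode, kind, campaign}`, `Wells` `{plate_barcode, well, campaign}`,
`Libraries` `{name, plate_format}`, each with a declared type; an insert
either succeeds or fails with the offending key named — never a silent
partial write. The required key sets are not fixed by any external
convention; they are the minimal set the downstream operations need, and
are declared in one place (`collection_schemas()`) as an explicit
assumption. Extra keys always pass through, which is what makes the store
useful for ad-hoc annotations (drop images, comments, instrument ids).

A campaign moves through `Plates → Cryo → Soaking → Redissolve → Fishing`.
`Cryo` and `Redissolve` are optional and may be skipped; the others may
not. A stage can be started or finished only when every earlier mandatory
stage is done, and finished stages cannot be reopened — the invariant the
tests drive at random is that no call sequence leaves a later mandatory
stage done while an earlier one is pending. Station file exchange is
modelled transport-agnostically: exports write a file, ingests consume a
report file; nothing in the contract requires a live socket.

## Soak design

Dispense targets are picked by clicking the drop image;
`pixel_to_offset()` converts a click to millimetres with the image
calibration (+x right, +y down), clamping to the drop half-extent with a
flag rather than erroring — a slightly wild click is a usable target, but
the operator should know.

The transfer list follows the cherry-pick CSV convention (source plate and
well, destination plate and well, volume, destination X/Y offsets). Two
conventions needed deciding:

* **Subwell encoding.** The three drops share one 96-well footprint, so the
  destination well column carries the plain well (`"B7"`) and the drop is
  encoded in the offsets: the configured per-drop centre offset plus the
  user's in-drop offset, written with 3 decimals. The encoding is isolated
  in the writer; a facility that addresses subwells as separate wells can
  change it there.
* **Volumes** are decimal nanolitres and must be exact multiples of the
  2.5 nL droplet quantum — the dispenser fires discrete droplets, so a
  26 nL request is a silent 10% error waiting to happen; we reject it.

`dmso_percent()` is the dilution identity
`100 · v / (V_drop + v)`; it is what you iterate on during DMSO
optimization before committing the full library. Soak timers are
per-record, floored to whole minutes to match the per-minute display
refresh, and frozen by the dispense report (`soak_stop`). Report rows are
matched on (destination plate, well + drop), first match wins; unmatched
or duplicate rows come back as a discrepancy table instead of raising,
because a half-failed dispense run is exactly when you need the partial
result. The DMSO-free variant (`plan_redissolve()`) fills an empty plate
row-major, drop-fastest (`A1a, A1b, A1c, A2a, …`) and returns a tracking
sheet with the dispense/dry/redissolve steps pending.

## Harvest merging

The harvesting robot reports per-drop outcomes in visit order; the barcode
station reports scanned puck/pin positions in mount order. There is no
shared key, so the join is by sequence: the k-th fished drop gets the k-th
scan; skipped and failed drops consume no scan. A count mismatch is a hard
reconciliation error naming both counts — guessing an alignment would
silently attach the wrong fragment to a dataset, the worst failure mode a
screen can have. When pin barcodes are scanned they are carried and can be
cross-checked, but a contradiction is flagged, not resolved. The
collection sheet (one row per fished crystal, sorted puck-then-pin, sample
name `campaign-plate-welldrop`, SMILES resolved from the library) is
exported as CSV.

## Campaign statistics

`campaign_summary()` computes the funnel — soaked, mounted, diffracting to
≤ 2.5 Å, RSCC ≥ 0.7, verified — with all percentages relative to crystals
soaked. Gating is sequential: the RSCC filter applies to datasets that
passed the resolution cutoff, and verification to RSCC passers, so the
funnel is monotone by construction and the code asserts it on input too.
Rounding matches how such tables are printed: whole percent for the
crystal-level rows, one decimal for the dataset-level rows, half away from
zero. The RSCC threshold is inclusive (0.7 passes). Verification is a
human judgement on the fitted density, so it enters as an input flag.
Resolution histograms use half-open bins `[lo, lo + w)` (an exact-edge
value goes up, with a 1e-9 epsilon guarding against binary-decimal float
noise), keep interior empty bins and drop leading/trailing ones.

## The synthetic-data generator

`simulate_campaign()` exists so the full pipeline — library SDF, soak plan,
transfer list, dispense report, fishing definition, shifter results, puck
scans, dataset results, summary — runs end to end from one seed with no
external data, producing byte-identical files on identical specs (the SDF
writer normalizes the converter's timestamp line for exactly this reason).

The default `fixture_spec()` emulates a full-scale campaign:

* **Scale**: two 96×3 plates (the test and acceptance runs use three
  plates × 187 drops = 561 crystals, a published campaign's scale; the
  default is desk-sized).
* **Harvest loss** `fish_skip_rate = 0.029` and
  `dispense_fail_rate = 0`: mounting ≈ 97% of soaked.
* **Resolution** ~ Normal(1.7, 0.55) Å truncated below at 0.9 Å. The mean
  is a typical post-optimization campaign average. The standard deviation
  is deliberately *not* the width of a real resolution histogram (those
  are much narrower): the generator has no separate "no usable dataset"
  channel, so the tail above the 2.5 Å cutoff stands in for crystals that
  fail to yield data, and 0.55 puts ≈ 92% of mounted crystals under the
  cutoff — the realistic funnel fraction. Histograms of simulated
  resolutions are therefore wider than real ones; tests about histogram
  *mechanics* are unaffected, but the generator should not be used to
  benchmark resolution-distribution models.
* **Triage** `rscc_pass_rate = 0.081` per dataset (passers draw RSCC in
  [0.70, 0.98], others in [0.05, 0.69]) and
  `verify_given_pass_rate = 0.854` — hit-rate territory of a few percent
  of soaked crystals.

What the generator does not emulate: spatial effects across a plate,
fragment-dependent binding (outcomes are independent Bernoulli draws, so
it cannot validate any claim that one fragment beats another), drop
images, instrument timing jitter, and partially-filled pucks beyond simple
sequential filling. Passing tests therefore demonstrate that the
bookkeeping, joins and statistics are correct under realistic volumes and
rates — not that any scientific conclusion about a real protein target
would hold.

Every stochastic test fixes its seed; the binomial-expectation checks
compare each funnel stage to its upstream-conditional expectation within
three standard deviations, which at n = 561 is loose enough to be stable
across seeds and tight enough to catch a systematically wrong rate.

## Limitations

* The document store is single-writer, file-backed; it preserves the
  validator contract of a server-backed document database, not its
  concurrency.
* The collection sheet is CSV; facilities needing a spreadsheet binary can
  convert it trivially.
* RSCC values are consumed, never computed — density fitting belongs to
  the refinement software.
* The MaxMin selection is exact greedy, not an optimal max-min-dispersion
  solver; for library-scale n (≈ 10³) greedy is the field's standard and
  runs in seconds.
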