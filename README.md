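# fragcampaign

Campaign management for crystallographic fragment screening.

Crystallographic fragment-based drug discovery soaks hundreds of protein
crystals, each with a different small fragment (< 300 Da), harvests them, and
looks for fragments bound in the electron density. Running such a campaign is
mostly a bookkeeping problem: a fragment library living in a 384- or
1536-well acoustic-dispenser source plate, crystals in 96-well sitting-drop
plates with three subwell drops each, a picklist telling the liquid handler
which source well to fire into which drop, harvest records pairing crystals
with puck/pin positions in the sample changer, and finally a funnel of
counts — soaked, mounted, diffracting, density-triaged, verified — that
yields the campaign hit rate.

`fragcampaign` implements that bookkeeping as a library for people who run
or simulate such campaigns: facility staff, method developers, and anyone
who needs the campaign statistics reproducible from the raw station files.

## What it does

* **Well addressing** — parse/format for `"B7c"`-style crystal-drop
  addresses (rows A–H, columns 1–12, drops a–c) and `"P24"`/`"AF48"`-style
  library wells (384 and 1536 formats), 0-based internally, with strict
  range errors.
* **Fragment libraries** — SDF ingest with per-record catalogue code and
  source well, SMILES canonicalization at ingest, CSV export, and greedy
  **MaxMin diversity selection**: repeatedly add the fragment maximizing its
  minimum Tanimoto distance (on 1024-bit path fingerprints) to the already
  selected set — the standard way a "most diverse *n*" screening subset is
  chosen.
* **Campaign store** — an embedded JSON-lines document store with
  per-collection validators (`Plates`, `Wells`, `Libraries`): an insert is
  accepted only if every required key is present with the right type, and a
  five-stage campaign state machine (`Plates → Cryo → Soaking → Redissolve
  → Fishing`, the two optional stages skippable) that refuses out-of-order
  progress.
* **Soak design** — click-to-millimetre dispense offsets, transfer lists in
  the cherry-pick CSV convention with the subwell drop encoded in the
  destination offsets, the 2.5 nL droplet-quantum volume check, DMSO
  percentage arithmetic, per-record soak timers (whole minutes, frozen when
  the dispense report lands), dispense-report ingest with discrepancy
  listing, and DMSO-free "redissolve" plate planning.
* **Harvest** — fishing definitions, sequence-based merging of harvesting
  results with puck/pin scans (skipped drops consume no scan), and the
  data-collection sample sheet with SMILES resolved per sample.
* **Statistics** — the campaign funnel with published-style rounding
  (integer percent for crystal-level rows, one decimal for dataset-level
  rows, half away from zero, all relative to crystals soaked), the
  inclusive RSCC ≥ 0.7 triage filter, and half-open resolution histograms.
* **Fixtures** — a deterministic synthetic-campaign generator that writes
  every file the laboratory stations would exchange, so the whole pipeline
  is testable end to end from one seed.

## Worked example

```r
library(fragcampaign)

# a synthetic 8-fragment library, then the 3 most diverse members
sdf <- fixture_library_sdf(tempfile(fileext = ".sdf"), n = 8, seed = 3)
lib <- read_library_sdf(sdf)
select_diverse(lib, 3)
#> [1] "FRAG0001" "FRAG0003" "FRAG0005"

# 25 nL of fragment stock into a 475 nL drop
dmso_percent(475, 25)
#> [1] 5

# the campaign funnel from pre-tabulated counts
campaign_summary(561, 545, 505, 41, 35)
#> Campaign outcome funnel
#>   crystals soaked                      561 (100%)
#>   crystals mounted                     545 (97%)
#>   diffracting to <= 2.5 A              505 (90%)
#>   datasets with RSCC >= 0.7             41 (7.3%)
#>   verified complexes (hit rate)         35 (6.2%)
```

The first picks are the carboxylic acid, the cyclic amide and the uracil —
mutually distant chemotypes — rather than three aromatics. The funnel says:
97% of soaked crystals were mounted, 90% gave a dataset at 2.5 Å or
better, 7.3% passed density triage and 6.2% were verified complexes — the
hit rate.

A shell entry point wrapping the same functions ships in
`inst/cli/fragcampaign.R` (`campaign new/list/status`, `plate add`,
`library select/export`, `soak plan`, `stats summarize/hist`,
`fixtures make`).

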