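---
title: "A file-based pseudonymization registry: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A file-based pseudonymization registry: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoreg)
```

## The problem

Multisite biomedical studies need to register subjects and biosamples at
the point of care, replace directly identifying data (IDAT) with stable
pseudonyms for all downstream data flows, and keep the identity-to-pseudonym
mapping local, access-controlled and auditable. `pseudoreg` implements this
as a plain R library over a local directory store: no server, no database,
no network dependency, which is what allows a site to be onboarded in hours
rather than months. Medical data (MDAT) are structurally unstorable — the
schema has only the configured identity fields plus non-clinical
`extra_properties` — so the privacy guarantee of the IDAT/MDAT split is a
property of the data model, not of policy.

## Pseudonyms and the check character

A pseudonym is `PREFIX-SITE-BODY-CHECK`. The body is drawn uniformly at
random from a 32-character alphabet (A–Z and 2–9 minus the visually
ambiguous I, O, 0, 1, since identifiers are read by humans off printed vial
labels). Random rather than sequential bodies mean exported artifacts do not
leak enrolment order. With the default body length 6 the space holds
$32^6 \approx 1.07\times10^9$ identifiers; validation warns when the space
is not comfortably above the study's expected capacity.

The check character implements ISO 7064 MOD 37-2, computed over the
concatenated `prefix + site + body` so that a mistyped site code is caught
too. The pure system with modulus 37 and radix 2 detects **every**
single-character substitution and every adjacent transposition that changes
the string; the test suite verifies this by exhaustive sweep against an
independent polynomial formulation of the standard
($\sum_i a_i 2^{n-i+1} \equiv 1 \pmod{37}$).

Collision-free generation uses bounded rejection sampling (64 rounds)
followed by a deterministic lexicographic scan, so generation terminates
with a typed capacity error — never an endless loop — when the space is
genuinely exhausted.

## Record linkage

Duplicate enrolment is prevented by a mandatory search before every
registration. Identities are first normalized: ICU transliteration to
ASCII, upper-casing, whitespace collapsing, strict ISO 8601 dates, canonical
enum codes. Normalization is idempotent, and all matching happens on the
canonical form.

Per-field similarities are

* **text** — Jaro–Winkler (prefix boost $p = 0.1$, prefix capped at 4),
  the standard choice for short name strings with keyboard typos;
* **date** — 1.0 if equal; 0.8 on a day/month transposition or when exactly
  one of year/month/day differs (the two common transcription slips);
  0.0 otherwise;
* **enum** — equality.

The linkage score is the weighted arithmetic mean over fields present in
both records; missing fields drop out and their weight is renormalized
away. The default weights follow Fellegi–Sunter agreement weights,
$\log_2(m/u)$ with $m \approx 0.95$: agreement on a birth date is worth
about 8 bits of evidence ($u \approx$ chance agreement of a calendar date),
a name about 6 bits, and sex only about 1 bit ($u = 0.5$). We initially
shipped near-uniform weights and found in error analysis on synthetic
cohorts that the sex field — which agrees between half of all random pairs —
was buying lookalike pairs a sixth of the score for free; re-weighting by
evidence content removed most lookalike false flags without touching a
single true duplicate. The weights are configurable per field in the study
configuration.

Scores classify against two thresholds, defaults `block = 0.98` and
`review = 0.85`: at or above `block` a registration is refused outright; in
`[review, block)` it requires an explicit, audited override.

### Blocking

Scanning every record for every search scales quadratically over a study's
lifetime, so candidates come from a union of inverted indexes: the
two-character prefix of every normalized text field, plus the full value of
every date field. A duplicate produced by a bounded typo process (at most
two edits, never touching every field) always leaves at least one of these
keys intact, so for that class of queries the blocked result is provably
identical to a brute-force scan — blocking is an optimization, not an
approximation, and the tests assert set-equality against an independent
brute-force oracle. A candidate is fully scored only if an optimistic
bound (cheap date/enum similarities plus weight-one text fields) can reach
the threshold; because text similarity is at most 1 this pruning is exact.

Scaling is asserted on *candidate comparison counts*, never on wall-clock
time: the per-search count must grow at most linearly in registry size
(it is in fact roughly the size of the largest shared name-prefix block).

## The synthetic cohort generator

Linkage quality cannot be measured on real enrolment data inside a test
suite, so `generate_cohort()` fabricates it with ground truth:

* names sampled from bundled multi-locale frequency lists (Zipf-like decay
  over ~120 first names per sex and ~230 surnames, with a ~30% generated
  rare-surname tail), dates of birth uniform over 1930–2009, sex F/M;
* a `duplicate_rate` fraction of records are copies of earlier originals
  with 1..`max_typos` logged edits — character substitution, adjacent
  transposition, deletion, and/or a day↔month swap — never touching every
  identity field at once;
* distinct originals are kept *separable*: a candidate identity that the
  default matcher would already flag against an earlier original (score at
  or above the review threshold) is redrawn. Separability is what makes the
  ground truth meaningful — any flagged record in a generated cohort is a
  true duplicate, so a recall shortfall indicts the matcher and a precision
  shortfall cannot be blamed on the data.

Everything is driven by one integer seed and is bit-reproducible.

What the generator deliberately does **not** emulate: households sharing
surnames and addresses, twins, transliteration variants of the same name
(`Müller`/`Mueller` entered at different sites), nicknames, or missing
fields. Passing the synthetic benchmarks therefore demonstrates that the
matcher handles the modeled typo process, not that it would reach the same
precision on messy production data; the review queue and the configurable
thresholds exist precisely because real data are harder.

At the reference conditions (n = 5000, 5% duplicates, ≤2 typos) the
default configuration reaches recall ≥ 0.95 and precision ≥ 0.90; the exact
values for a given seed are computed by `evaluate_linkage()` and by
`scripts/acceptance.R`.

## Registry semantics

The store is a directory: `config.yaml`, the record journals
`subjects.csv` / `biosamples.csv` (append-only; saving appends only rows not
yet persisted), `audit.tsv`, `meta.json`, and `lock.json` while a writer is
active. Single-writer semantics mirror office-file workflows but with safer
failure modes: a second writer fails naming the current holder; a lock
older than 12 h is *stale* and can only be taken over with an explicit
flag, never silently. Readers open consistent snapshots of the durable
files without blocking the writer.

Every mutating operation and every depseudonymization appends exactly one
audit entry (UTC timestamps with offset; multi-country deployments disagree
on local time). Reidentification is deliberately noisy: a pseudonym that is
well-formed but fails its check character raises a *suspected transcription
error*, distinct from not-found, because a mistyped character is the far
more likely cause. Backup reminders are computed from the configured
interval and surfaced by the CLI on every mutating command.

Bulk import is row-atomic: each row is accepted, rejected (with a reason)
or flagged as a duplicate independently — with one exception, a pseudonym
collision in restore mode aborts the whole file with a diff report, since a
partially restored backup is worse than none.

## Labels

Each biosample label carries the biosample ID, the owning subject ID, the
visit and sample-type display labels, and a machine-readable code whose
content is exactly the biosample ID. Three symbologies are implemented in
package code — DataMatrix ECC200 (squares 10×10..26×26, ASCII encodation,
Reed–Solomon over GF(256) with polynomial 0x12D), QR (byte mode, versions
1–3, error-correction level M, mask 0, polynomial 0x11D) and Code 128
(set B) — each with a matching decoder used for round-trip verification.
The decoder checks Reed–Solomon syndromes and refuses corrupted symbols
rather than attempting correction: a vial label that does not scan cleanly
should be re-printed, not guessed at. Sheets are rendered as a single
self-contained HTML document (all code graphics inlined as SVG, no external
resources), so printing works in any browser on an offline machine and no
label data leave the device.

## Numerical and design choices

* Problem sizes in the shipped tests: the uniqueness sweep generates 10^5
  pseudonyms and brute-forces ~4.5×10^5 substitutions and ~10^4
  transpositions; linkage quality runs at n = 5000; search/oracle
  equivalence at 1000 records × 200 queries; the import experiment at 10^5
  subjects plus 10^5 biosamples with comparison counts sampled at
  10^3/10^4/10^5.
* Ties in search results are broken by pseudonym string order after score,
  so output order is deterministic.
* Dates are ISO 8601 everywhere; anything else is a validation error, not a
  guess — eleven countries means eleven local date conventions.
* Degenerate linkage inputs (no comparable fields) raise a typed error
  rather than returning 0, since "no evidence" and "strong non-match" must
  not be conflated.
* Precision/recall conventions: with no positives and no false positives
  both are defined as 1.0.

## Known limitations

* No phonetic encodings (Soundex/Metaphone) and no cross-site federated
  linkage; matching is within one registry.
* The QR encoder covers byte-mode versions 1–3 (42 bytes at level M) —
  ample for identifiers, not for arbitrary payloads.
* The file store trusts the filesystem for durability; the backup-reminder
  discipline, not journaling, is the recovery story.
* Linkage quality figures are properties of the synthetic typo model; see
  the generator section above for what that does and does not show.
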