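---
title: "Privacy-preserving record linkage with CLKs and multibit trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving record linkage with CLKs and multibit trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Medical and administrative datasets frequently have to be linked at the
person level without a shared unique identifier, and privacy law often
forbids releasing names and dates of birth to whoever performs the linkage.
Privacy-preserving record linkage (PPRL) solves this by encoding the
identifying fields at the data custodian into a representation that still
supports *approximate* comparison — so that "SMITH, ANNA, 1990-07-03" and
"SMITH, ANA, 1990-07-03" still look similar — while individual values cannot
be read back out.

`clklink` implements one complete PPRL stack:

1. **CLK encoding** — every record becomes a single composite Bloom filter,
   the *cryptographic long-term key*;
2. **multibit-tree retrieval** — all record pairs whose Tanimoto (Jaccard)
   similarity meets a threshold are found exactly, without comparing all
   \(O(n^2)\) pairs;
3. **evaluation** — pairwise precision/recall/F against a truth set;
4. **synthetic data** — populations with known truth, configurable
   duplication, typos and missingness, standing in for restricted
   real-world hospital data.

## The CLK model

Each identifier field of a record is decomposed into q-grams — overlapping
bigrams for free-text fields (`ANNA` → `_A AN NN NA A_` with boundary
padding) or unigrams for short near-numeric fields (dob, sex, postcode).
Every gram is hashed \(k\) times into a bit vector of length \(\ell\); a
record's CLK is the union of all its grams' bits.  Two CLKs are compared
with the Jaccard/Tanimoto similarity over set bits,

\[ J(A,B) = \frac{|A \cap B|}{|A \cup B|}, \]

so shared grams raise similarity smoothly and a single typo (which disturbs
at most two bigrams, hence at most \(2k\) bits in each direction) degrades
it only slightly.  The Dice coefficient \(D = 2|A\cap B|/(|A|+|B|)\) is also
provided; the two are monotonically linked by \(J = D/(2-D)\), which the
test suite asserts to \(10^{-12}\).

Defaults: \(\ell = 1000\), \(k = 10\), inclusive threshold comparison
(similarity \(\ge t\) is a match — note this convention changes pair counts
and is applied consistently everywhere).

### Hashing choices

* **Keyed digests.** Positions are derived from HMAC-SHA256 under a
  required secret, not from plain public hash functions, so a CLK file
  cannot be dictionary-attacked by re-encoding candidate names with public
  code.  The secret is never written to any output, log or printed object.
* **Random hashing (default) vs double hashing.** The classical
  construction derives positions as \(h_1 + i\,h_2 \bmod \ell\); published
  frequency attacks exploit exactly that structure, and full random hashing
  (an independent keyed digest per iteration, the iteration index mixed
  into the key) prevents them.  Double hashing is retained as an option
  only for comparability with the original construction.
* **Field tagging (default on).** Grams are prefixed with their field name
  before hashing, so `ANNA` as a first name and `ANNA` as a surname set
  different bits.  The original CLK formulation mixes fields
  indistinguishably; switch `field_tagging = FALSE` for fidelity to it.
* **Salting.** Optionally a stable per-record field is concatenated into
  the key material (`salt_field`), hardening against frequency analysis at
  the cost that only records agreeing on the salt can match.
* **Positional unigrams (default off).** A Bloom filter stores a *set* of
  grams, so unigram fields lose multiplicity and order: dobs 19900703 and
  19900730 have identical digit sets and therefore identical contributions.
  `positional_unigrams = TRUE` prefixes each unigram with its index, making
  equal contributions equivalent to equal values.  This matters for exact
  de-duplication (see the perfect-recovery test below).

### Parameter sets

Four presets mirror typical linkage-variable choices: `set1` (first name,
last name, dob, sex), `set2` (all eight fields), `set3` (set 1 + suburb +
postcode), `set4` (set 1 + middle name).  Gram modes default to bigrams for
names/addresses and unigrams for dob/sex/postcode — short numeric fields
lose typo robustness as bigrams — and are configurable per field, since the
original study does not report its field-to-mode mapping.

## Multibit trees

A Tanimoto threshold query must be *exact*: blocking that silently loses
true pairs corrupts downstream quality estimates.  The multibit tree gives
lossless pruning:

* **Popcount binning.** CLKs are grouped by popcount.  For a query with
  \(a\) set bits and a bin of popcount \(b\),
  \(J \le \min(a,b)/\max(a,b)\), so whole bins outside
  \([t\,a,\; a/t]\) are skipped.
* **Split-half trees.** Within a bin, the tree splits on the bit whose
  set/unset counts among current members are closest to half (ties: lowest
  bit index, so trees are deterministic).  Each edge records a *match bit*
  — a position where every record below has a known value.
* **Upper-bound pruning.** With \(M_1/M_0\) the accumulated match bits of
  value 1/0 on the path, the intersection with any record below is at most
  \(i_{\max} = \min(a - |\{p \in M_0 : q_p = 1\}|,\; b - |\{p \in M_1 :
  q_p = 0\}|)\), giving the bound \(i_{\max}/(a + b - i_{\max})\), which is
  non-increasing down any path.  Subtrees whose bound falls below \(t\) are
  discarded; leaf survivors are verified with the exact similarity.

Numerical note: both the bound and the true similarity are single correctly
rounded divisions, and rounding is monotone, so a rational inequality
\(\text{bound} \ge J\) survives into floating point — pruning can never
lose a qualifying pair to rounding.  The recursion splits each bit at most
once per path, and the query traversal uses an explicit stack, so
\(\ell = 1000\) cannot overflow call depth.

Leaf limit defaults to 1 (the study's setting).  A leaf may hold more
members only when they are bit-identical (no discriminating bit exists).
Trees are in-memory and rebuilt per run; there is no serialization.

## Linkage engine and blocking

`deduplicate()` builds one tree and queries every CLK against it,
canonicalizing to unordered pairs; `link_datasets()` indexes the left file
and queries the right.  The engine emits raw candidate pairs — no
transitive closure, no one-to-one assignment — because downstream users
differ on clustering policy.

`external_block()` partitions records by a derived key (e.g. year of birth
from dob) before per-block de-duplication.  Block labels are keyed hashes
when a secret is supplied, so clear-text keys never sit beside CLKs.
Records with a missing key form their own block rather than being compared
to everything — cheaper, but a documented recall cost.  Blocked output is
provably the unblocked output restricted to within-block pairs; the engine
logs per-block sizes, pair counts, similarity evaluations and node visits
so the comparison-work saving is auditable.

## Evaluation

Pair-level precision = TP/(TP+FP), recall = TP/(TP+FN), F = harmonic mean.
Degenerate denominators follow the conventional value 1.0 (logged), so
sweeps never crash at an empty end of the threshold range.
`threshold_sweep()` runs one de-duplication at the most permissive
threshold and filters upward — valid because pair sets nest exactly (each
pair carries its exact similarity).

## The synthetic world

`generate_entities()` draws fully populated records from small bundled
frequency tables (Zipf-weighted given names by sex, surnames, suburb/
postcode pairs, street addresses; dobs uniform over 1915–2005).  The tables
are deliberately tiny: they produce realistic value collisions and name
lengths, not demographic fidelity, and nothing is downloaded.

`make_duplicates()` gives each entity a Poisson(`dup_rate`) number of
duplicate records — admissions per person are counts, not fixed — each
independently corrupted: with probability `field_swap_rate` first/last
names swap, and each name/suburb/address field receives exactly one edit
(insert/delete/substitute/adjacent-transpose, equal weight) with
probability `typo_rate` (default 0.15, a deliberately noticeable but small
clerical-error rate; the real datasets' error rates are unreported).
Missingness is then applied per field to originals and duplicates alike, so
observed marginal missingness matches the configured profile; the
`nsw_public`, `nsw_private` and `wa` profiles reproduce the reported
missing-value percentages of the source datasets ("<1%" modeled as 0.5%),
with `nsw_private` modeling the stratum whose name fields are entirely
absent.  Default `dup_rate` is 0.5 — the real duplicate-per-person
distribution is unreported; this value is an arbitrary, documented choice.

Dates of birth are never typo-edited: an edit could leave the canonical
`YYYYMMDD` space, and dob transcription error is not part of this model.
Corrupted values are re-normalized so the "stored values are normalized"
invariant survives corruption.

What a green test does **not** establish: real name-frequency distributions
(the bundled tables are far smaller than a national population), correlated
missingness beyond the all-names-missing stratum, household/address
correlation, or genuine clerical behavior.  Quality numbers computed on
this synthetic world characterize the *pipeline*, not the source study's
datasets.

## Design decisions that were genuinely open

* **Perfect-recovery testing uses positional unigrams.**  The acceptance
  property "zero corruption ⇒ precision = recall = 1 at threshold 1"
  presupposes that distinct entities with distinct identifiers get distinct
  CLKs.  Under unordered digit unigrams that is false by construction
  (equal digit multisets collide), so the perfect-recovery test enables
  `positional_unigrams = TRUE`, the encoding under which CLK identity
  coincides with identifier identity.  The default stays off for fidelity
  to the classical construction — and the default encoding's dob-collision
  false positives are visible in the missingness-degradation experiments,
  which is faithful to how set-1-style keys behave.
* **Degenerate one-character bigram values** emit the character itself as a
  gram rather than nothing, preserving information.
* **All-zero CLKs** (every included field missing) are encoded, logged and
  flow through as non-matches (similarity 0 by convention) rather than
  erroring — missingness is a first-class property of the data.
* **Unparseable dates** normalize to missing with a logged warning; loads
  never abort or silently drop rows (input row count = output record
  count, asserted in tests and auditable from logs).
* **Normalization itself** (uppercase, collapse whitespace, strip
  punctuation from name-like fields, `YYYYMMDD`) is a package choice — the
  study does not describe its preprocessing — tuned to maximize gram
  stability across clerical variants, and idempotent.

## Limitations

* Exact bitwise reproduction of the source study's CLKs is impossible: its
  hash primitives, keys, per-field gram modes and padding convention are
  unreported.  The package reproduces the construction, not the bits.
* Attack implementations, record-level Bloom filters with per-field bit
  weighting, phonetic encodings, address standardization and
  Fellegi–Sunter weighting are out of scope.
* Runtime at the study's scale (millions of records) is not a target here;
  the engine is exercised and timed at \(10^3\)–\(10^4\) records.
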