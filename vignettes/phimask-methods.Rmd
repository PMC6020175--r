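---
title: "Methods: sliding-window PHI masking and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window PHI masking and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phimask)
```

## The model

`phimask` implements dictionary-driven de-identification: the queries are
the patient's own identifiers as held in structured administrative fields,
and the task is approximate string search, not named-entity recognition.
The core assumption is that the structured record is *clean* while the
text is *noisy* — misspelt, abbreviated, truncated, or damaged by OCR. The
masker therefore needs no training data and no hand-crafted rules, but it
can only remove identifiers it has been given; it is not a general PHI
detector.

For a PHI token $t$ with $L = |t|$ code points, the scan visits every
character offset $i$ of the document and every window width
$w \in [\max(1, L-\Delta),\, L+\Delta]$ with
$\Delta = \lceil \text{width\_slack\_fraction} \cdot L \rceil$, computing

$$ s(t, x_{i:i+w}) \;=\; 1 - \frac{d(t,\, x_{i:i+w})}{\max(L, w)} $$

where $d$ is the unit-cost Levenshtein distance. Every window with
$s \ge \theta$ is masked; overlapping hits union. Masking replaces each
covered code point with `mask_char`, so the output has exactly the input's
length and all downstream character offsets remain valid. One dynamic
programming table per offset yields the distances to *all* window widths
at once (the DP's last row), so the scan costs
$O(nL(L+\Delta))$ per token and is implemented in C++ on integer code
points (offsets count Unicode code points, never bytes).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `theta` | 0.63 | similarity threshold in [0,1]; calibrated, see below |
| `width_slack_fraction` | 0 | window widths $L \pm \lceil fL \rceil$; 0 = fixed-width windows |
| `min_token_length` | 3 | queries shorter than this are skipped |
| `mask_char` | `"X"` | in-place masking character |
| `case_fold` | `TRUE` | compare case-insensitively |
| `whitespace_barrier` | `TRUE` | windows never span whitespace |
| `coverage_threshold` | 0.3 | fraction of a token's characters that must be masked for it to count as detected |

Two geometry choices deserve explanation, because the published account of
this algorithm family does not pin them down.

**Whitespace barrier.** A PHI token contains no internal whitespace (a
data-model invariant), so a window holding a space can never be a verbatim
token occurrence; admitting such windows mainly lets matches bleed across
word boundaries. More decisively, the published validation results for
this approach show per-token recall collapsing under whitespace-insertion
noise (to roughly 11% at a 20% insertion rate) — arithmetic that is only
reproducible if the matcher effectively never matched a token across an
inserted space. With raw-text windows and generous width slack, our
implementation absorbed single space insertions easily and overshot the
reference recalls by 12–36 percentage points. The barrier is therefore the
default; setting `whitespace_barrier = FALSE` restores unrestricted
windows.

**Fixed-width windows (slack 0).** Width slack exists to absorb
insertions and deletions that change the surface length of a token. With
the barrier active, its remaining effect is matching *fragments* of words
(edge deletions), which again inflates recall under OCR noise beyond the
published degradation profile, and widens the false-positive surface.
The shipped default is therefore $\Delta = 0$: a token of length $L$ is
compared against every in-word window of exactly $L$ characters. Slack
remains a first-class parameter for uses where partial-occurrence
tolerance matters more than replicating the reference behaviour.

**Threshold semantics.** The algorithm family is described as masking
when the distance is *above* a threshold, which taken literally would
mask dissimilar text. Tolerance of misspellings requires the opposite
reading, so `phimask` masks when the *normalised similarity* is at or
above `theta` — equivalently, when the distance is below a length-scaled
cutoff. The threshold is expressed as a similarity so that one value
behaves sensibly across token lengths.

**Calibration.** The reference publication reports benchmark outcomes but
neither its threshold nor its token-detection rule. Both free scalars —
`theta` and `coverage_threshold` — were calibrated *once*, on a single
condition (keyboard substitution at a 3% per-character rate, 1000
documents), by grid search minimising the Euclidean distance to that
condition's published precision/recall point; the optimum (0.63, 0.3)
became the package default and was then frozen for every other condition.
No other condition, and no other parameter, was tuned. Note that with
integer edit distances the threshold acts through
$\lfloor (1-\theta) L \rfloor$, so the effective grid of distinct
behaviours is coarse: values of `theta` through roughly 0.58–0.66 behave
identically on short tokens.

## The mutation models

* `keyboard` — each alphanumeric character is independently replaced,
  with probability `char_rate`, by a uniform draw from its QWERTY
  physical-neighbour set (case preserved; punctuation and spaces never
  substituted, so tokenization is stable). The published description
  invokes prior probabilities of frequently mistyped keys without
  publishing the table; uniform physical adjacency is the neutral choice,
  and the adjacency map ships as a data file so alternative confusion
  priors can be swapped in.
* `alias` — tokens with an entry in the involutive full-form ↔
  abbreviation dictionary (Road↔Rd, Street↔St, …) are swapped with
  probability `token_rate` (benchmark value 1: every eligible token).
* `truncate` — with probability `token_rate` the address is cut from the
  end to exactly `min_tokens` (= 3) tokens, emulating unrecorded
  supplemental address lines. Cutting to *exactly* the minimum (rather
  than a random length) follows from the reference benchmark's truncation
  row averaging three gold tokens per document.
* `ocr` — keyboard substitution at `char_rate`, then a single space
  inserted independently with probability `ws_rate` after each character
  except the last. Exactly one space per triggered gap; output length ≥
  input length.

All mutators are the identity at rate 0, and identical (input, spec,
seed) triples give identical output.

## The synthetic corpus

Each document carries one synthetic address drawn from a fixed grammar —
house number (1–999, uniform), one or two street-name words, a
thoroughfare type, a district word, a town word, zero to two region
words, and a UK-shaped postcode pair (`LLN NLL`) — for 7–10 tokens per
address, mean ≈ 8.5, i.e. roughly 8 500 gold address tokens per
1000-document corpus. The mutated tokens are embedded, space-joined, at a
random sentence boundary inside 3–8 lorem-ipsum sentences (5–12
pseudo-Latin words, no digits), and one gold annotation per surviving
token records its exact offsets. The PHI table always holds the clean,
unmutated tokens: the masker never sees the mutated form.

Design notes:

* The thoroughfare lexicon mixes the ten abbreviable types of the alias
  dictionary with twelve non-abbreviable ones (Way, Close, Walk, …),
  drawn uniformly — a realistic mix for UK addresses. It caps the
  alias-condition recall: an abbreviated surface form ("St") is both too
  short and too distant from its full query ("Street") to be recovered,
  so roughly one token in two addresses is structurally unmaskable there.
* House numbers of one or two digits (about 10% of addresses) fall under
  `min_token_length` and are structurally missed; this bounds recall even
  on an unmutated corpus at about 98.8%, and is the dominant miss in the
  truncation condition, where each document retains only three tokens.
* The filler lexicon is fixed and shipped in-repo so false-positive rates
  are reproducible; it is not filtered for similarity to address words.
  This is the least controlled aspect of the emulation: the fuzzy
  collision structure between *our* pseudo-Latin filler and *our*
  address vocabulary differs from whatever the original company-registry
  addresses and generated filler produced. The consequence is visible in
  the benchmark: at the calibrated threshold our corpus yields
  proportionally more false positives in conditions with many unembedded
  queries (truncation) and noisy surfaces (OCR) than the reference
  reported, while the keyboard and alias conditions track it closely.
* One address per document; multi-address documents are out of scope for
  the benchmark.

## Scoring

Counts are pooled corpus-wide (micro-averaged). A gold token counts as
detected when at least `coverage_threshold` of its characters are masked.
Gold spans containing whitespace — produced only by the OCR mutator — are
scored *per whitespace-delimited fragment*: a token split into "Mea dow"
contributes two countable units. This follows the reference accounting,
whose OCR-condition gold totals grow with the insertion rate exactly as
fragment counting predicts (≈ 8 500 · (1 + (L̄−1)·rate)). False positives
are the non-gold whitespace-delimited tokens of the document (tokens
without a single alphanumeric are ignored) whose masked fraction reaches
the same threshold. Undefined ratios (zero denominators) are reported as
`NA`, and printed as empty cells.

## The benchmark

`run_benchmark()` evaluates eight conditions in fixed order — keyboard at
3/10/20%, alias at token rate 1, truncation to three tokens, OCR at
(3,3)/(10,10)/(20,20)% — generating a fresh corpus per condition (seed =
base seed + condition index), de-identifying every document against its
clean record, and scoring. On one CPU the full run at 1000 documents per
condition takes on the order of two minutes. `compare_to_reference()`
sets the result beside the published reference values and reports
percentage-point differences. On any fixed seed, recall decreases
strictly across the keyboard rates and across the OCR rates, with OCR the
worst-recall family at matched rates — the central qualitative behaviour
of the method under degrading input.

The test suite exercises the pieces at these sizes: the full
1000-document benchmark once; metric-axiom checks of the edit distance
against an exhaustive-recursion oracle on strings of up to eight
characters; scan results against a brute-force window oracle; gold-span
integrity over ten thousand generated documents; and job-runner
partition-transparency and idempotence checks on small corpora.

## Degenerate inputs and numerical conventions

Offsets are 0-based, half-open, in code points. `edit_distance("", x)` is
`nchar(x)`; similarity of two empty strings is 1. Empty documents
de-identify to empty masked documents. An empty job produces a completed
state with zero partitions. Ties between overlapping window hits are not
broken — all qualifying windows mask. Any optimisation of the scan must
stay bit-identical to the brute-force reference semantics, which the
oracle tests enforce.

## Limitations

Passing this benchmark shows the matcher recovers *synthetically*
corrupted identifiers from clean queries under controlled noise; it does
not show performance on real clinical text, whose typo distribution,
formatting variety and narrative vocabulary differ. Non-address
identifiers (names, phone numbers, NHS numbers) pass through the same
matcher but are not separately benchmarked. The alias dictionary is
deliberately small and address-specific. Deletion and transposition typo
classes are not simulated.
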