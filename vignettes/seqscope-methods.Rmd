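---
title: "seqscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqscope)
```

seqscope is a streaming quality-control engine for sequencing reads. It
makes one pass over a Sanger FASTQ file (plain or gzip), a FASTQ pair, or
an unaligned BAM, and feeds every read to a set of independent analysis
modules. This vignette explains the statistics each module computes, the
tunable parameters and their defaults, the synthetic-data generator used
throughout the test suite, and the design decisions taken where more than
one reasonable choice existed.

## Per-read quality: expected-error averaging

A Phred score $Q$ encodes an error probability $p = 10^{-Q/10}$. Error
probabilities average meaningfully; Phred scores do not. seqscope's
per-read mean quality is therefore

$$\bar Q_{\mathrm{EE}} \;=\; -10\,\log_{10}\!\Big(\tfrac{1}{L}\sum_{i=1}^{L} 10^{-q_i/10}\Big),$$

the Phred transform of the mean expected error rate. The arithmetic mean
$\bar Q_{\mathrm{ar}} = \tfrac1L\sum_i q_i$ is also computed, purely as a
comparison mode: by Jensen's inequality $\bar Q_{\mathrm{ar}} \ge \bar
Q_{\mathrm{EE}}$ for every read, with equality only when all base
qualities are equal, so arithmetic averaging systematically overstates
read quality whenever quality varies within a read — which it always does
on real data, drastically so on nanopore data. Both per-read histograms
are binned at the floor of the real-valued mean (bins 0–93), which makes
"reads ≥ Q15"-style counts exact with respect to the binning.

```{r jensen}
q <- c(10, 20)
read_mean_quality_arithmetic(q)
read_mean_quality_expected_error(q)
```

Per-position quality is aggregated both as the mean Phred score and as the
Phred of the mean error probability; reports show the expected-error
version by default.

### Position binning for long reads

Per-position statistics are exact up to position 500. Beyond that,
positions fall into geometrically growing bins (width ×1.1 per bin,
rounded, minimum 1), which bounds the profile at a few hundred rows even
for megabase nanopore reads. The binning is a memory-bounding choice of
this implementation, documented here rather than claimed to match any
other tool.

## Adapter probes (single-end)

Every read is scanned for a set of 12 bp probes — prefixes of Illumina
TruSeq/Nextera adapters and ONT ligation/rapid adapters, each also present
as a separately labelled reverse-complement entry, so strandedness is
always explicit. Matching is exact (no mismatches): the matcher packs each
probe into a 24-bit 2-bit-per-base code and slides a rolling code over the
read, a fixed-length dictionary automaton whose output is identical to
naive substring scanning (the suite verifies this equivalence exhaustively
on a reduced alphabet and on randomized reads). `N` has no code, so no
probe ever matches a window containing `N`. Only the leftmost hit per
probe per read enters the position histogram: adapter-content curves count
reads, not occurrences.

## Paired-end overlap and insert size

For a pair $(r_1, r_2)$, seqscope reverse-complements $r_2$ and evaluates
every ungapped alignment offset against $r_1$. An offset qualifies when
the overlap spans at least `min_overlap` (default 10) bases with a
mismatch fraction at most `max_overlap_error` (default 10%); among
qualifying offsets the one with the most matching bases wins, ties going
to the smallest insert size. The winning offset implies the insert size;
when the insert is shorter than a read, the bases past it are read-through
adapter and their 0-based start position equals the insert size.

Design notes: the scan is ungapped (indels inside a genuine overlap are
rare at these lengths and would only perturb the insert estimate by their
size); mismatch counting is quality-blind; `N` counts as a mismatch.
Failure to find a qualifying offset is a result ("undetermined"), not an
error, and the insert histogram keeps an undetermined bin so pair counts
are conserved.

## Duplication estimation

Each read is reduced to a 16 bp fingerprint: 8 bases from a front window
and 8 from a back window, both moved `min(64, L − 16)` bases inward. The
inward offset skips the read starts/ends where adapters and barcodes live
(ONT reads especially), so fingerprints reflect the insert, not the
library chemistry. Reads shorter than 16 bases use the whole read
left-padded with `A`; `N` maps to `A` deterministically; empty reads get a
distinguished empty fingerprint counted separately.

Fingerprints stream into an adaptive hash-threshold sketch. At depth $d$ a
fingerprint is tracked iff $h(f) \bmod 2^d = 0$, where $h$ is a fixed
published 32-bit mixing finalizer (lowbias32-style xor-shift/multiply
rounds) applied to the 2-bit-packed fingerprint — fully deterministic, no
per-run salt, so runs are reproducible. When the tracked set exceeds its
capacity (default $10^5$; the test suite exercises $10^3$), $d$ increments
and entries failing the tighter criterion are evicted, counts discarded.
Because the criteria are nested, batch insertion is exactly equivalent to
one-at-a-time insertion, and a fingerprint surviving to the end has its
exact total count.

The estimated distinct count is $|{\rm tracked}| \cdot 2^d$, and the
deduplicated fraction divides by the reads inserted. Below capacity
($d = 0$) the profile equals exact counting. Under sampling the estimator
is unbiased but noisy: for $D$ distinct fingerprints the standard
deviation of the estimate is $\approx \sqrt{D\,2^d}$, about 2–3.5
percentage points of a $10^5$-read stream at capacity $10^3$. The test
suite therefore checks the *mean* estimate over 100 seeds against the
exact truth (within 1 percentage point), not single-seed agreement. The
multiplicity histogram (distinct sequences seen $m$ times, capped at an
"≥16" bucket) scales tracked counts by $2^d$ and is approximate after any
eviction; the report labels it so.

## Overrepresented fragments

One read in eight (by 0-based stream index, `index %% 8 == 0`) is cut into
non-overlapping 21 bp fragments; long reads contribute at most 8 evenly
spaced fragments so they cannot dominate. The first 5 million distinct
fragments are stored; once the table saturates, existing fragments keep
counting but no new keys are admitted. A fragment is flagged when its
count exceeds 0.1% of the *sampled reads* (strict inequality). The
denominator choice — reads, not fragments — makes the threshold
interpretable as "this sequence occurs in more than 1 in 1000 sampled
reads".

Fragment length 21 is odd, so no fragment is its own reverse complement.
Note that with only ~1250 sampled reads (a 10^4-read library) a singleton
fragment sits at 0.08%, just below the threshold; libraries below ~8000
reads will flag singletons. The threshold is calibrated for
production-scale inputs.

Flagged fragments are identified against a contaminant database (a
UniVec-style FASTA; a 20-entry fixture of synthetic vector segments plus
published Illumina/ONT adapter sequences is bundled, and a full UniVec
file can be supplied instead). Candidates are entries sharing at least one
canonical 16-mer with the fragment — canonical meaning the lexicographic
minimum of the k-mer and its reverse complement, which covers both strands
with one index. Each candidate is aligned by Smith–Waterman (both fragment
orientations) and the best hit is reported when identity ≥ 0.80.

A limitation worth knowing: a 21 bp fragment yields six 16-mer windows,
all of which cover positions 6–16, so a substitution in that central
region leaves no clean window and candidate gathering fails even though
alignment identity would be 20/21. Sequencing errors land uniformly, so
roughly half of singly-mutated fragments still gather candidates, and
genuinely overrepresented fragments are dominated by their unmutated form,
which gathers perfectly. Larger fragments or a smaller k would trade this
off against index size and false candidates.

### Smith–Waterman scoring

Local alignment with affine gaps, match +2, mismatch −3, gap open −5, gap
extend −2; a gap of length $k$ costs $5 + 2k$ (the first gap base pays
open + extend — the convention used by EMBOSS and Biostrings, which lets
the suite cross-check scores against an independent aligner). Identity is
matches over alignment columns along the traceback of the best cell.
Tie-breaking is deterministic: the first maximal cell in row-major order,
traceback preferring diagonal over up over left. `N` matches nothing. The
suite verifies scores against a brute-force enumeration oracle on tiny
strings and against Biostrings on randomized pairs.

## Platform metrics

Illumina tile ids come from Casava-style colon-delimited names (field 5 of
7+); unparseable names contribute nothing, never an error. Per-tile
quality is the mean per-read expected-error quality, reported with its
deviation from the run mean, FastQC-heat-map style.

ONT metadata is read from `ch=`, `start_time=` and `duration=` comment
tokens; the uBAM reader synthesises the same tokens from the `ch`, `st`
and `du` tags, so FASTQ and uBAM containers yield the same metrics (up to
the float32 precision of BAM numeric tags). Translocation speed is read
length over duration (bases/second), aggregated as a histogram (25 b/s
bins) and as a time series over the run span (span/100 bins, minimum 1
minute). When only a start time is present the speed is reported
unavailable rather than inferred. Report sections activate only where
their metadata exists.

## Input handling

The FASTQ parser is strict by design: records are exactly 4 lines
(multi-line wrapped FASTQ, which no modern sequencer emits, is rejected),
qualities are Sanger offset-33 with a ceiling of Q93 — a quality character
below `!` or above `~` is a hard error rather than a silent clamp, which
catches offset-64 files immediately. Lowercase bases are uppercased and
IUPAC ambiguity codes other than ACGTN become `N`, since every module
assumes a 5-letter alphabet. uBAM records flagged as aligned are processed
from SEQ/QUAL as stored, with a counted warning; a missing QUAL field is
an error. Paired streams are validated positionally: canonical names
(after stripping one trailing `/1`/`/2`) must match at every index.

## The synthetic-data generator

`generate_library()` produces the study libraries every test runs on, with
a per-read ground-truth manifest. Its defaults are the conditions the test
suite documents:

* **Quality model**: per-base two-state Markov chain, high ≈ Q36 / low ≈
  Q12 (±2 jitter), persistence 0.95 per base, symmetric states. The
  stationary mix gives a mean arithmetic quality near Q24 while runs of
  low-quality bases pull the expected-error mean to ≈ Q15 — the structure
  that separates the two averaging modes measurably, as on real data.
* **Duplicates** are exact copies of other reads made before error
  injection, so the manifest's deduplicated fraction is exact by
  construction.
* **Paired mode** draws inserts from a truncated normal; whenever the
  insert is shorter than the read, both mates read through into the
  adapter at a position equal to the insert size.
* **Spikes**: adapters are planted fully inside the 3' half of single-end
  reads (position recorded); contaminants overwrite the read prefix.
* **ONT mode** emits channel (uniform 1–512), translocation speed
  (normal, 400 ± 40 b/s) and start times over a 20-hour window.

What the generator does **not** emulate: realistic error profiles
(homopolymer indels, quality-error correlation), GC bias, optical
duplicates, or platform-specific base-composition artefacts. Passing tests
demonstrate the correctness of the statistics and the estimators under
controlled conditions, not robustness to every artefact of real chemistry.

## Problem sizes used by the test suite

The suite runs on libraries of $10^3$–$4\times10^4$ reads (up to $10^5$
fingerprints per stream for the duplication study, 100 seeds per duplicate
fraction), exhaustive matcher verification over all $\le 20$ bp reads on a
two-letter alphabet, and brute-force alignment oracles up to 12 bp. These
sizes were chosen so every distributional claim is measured with adequate
Monte-Carlo precision while the whole suite stays fast enough to run
routinely.

## Known limitations

* Exact probe matching only; a single sequencing error defeats a 12 bp
  probe. Paired-end overlap detection, which tolerates 10% mismatches, is
  the stronger adapter detector where pairs exist.
* The duplication profile is approximate after eviction, and fingerprint
  collisions (two distinct reads sharing a fingerprint) bias the distinct
  count down by roughly the birthday rate of the 32-bit space — negligible
  below $10^7$ reads.
* The multiplicity histogram discards counts on eviction rather than
  rescaling them; multiplicities of rare survivors are exact, but the
  histogram's coverage shrinks by $2^{-d}$.
* Central substitutions in 21 bp fragments can defeat k-mer candidate
  gathering (see above).
* uBAM numeric tags are float32; durations round-trip at single precision.
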