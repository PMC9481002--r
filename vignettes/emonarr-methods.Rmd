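---
title: "Methods: emotion-tagged narrative analysis with emonarr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion-tagged narrative analysis with emonarr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Semi-structured clinical interviews can be segmented into *emotional
narratives*: contiguous discourse units in which the speaker stays on one
topic/emotion, each annotated by human coders with one of five primary
emotions (HAPPY, SAD, ANGRY, FEAR, DISGUST) plus subcategory codes from a
21-way affect taxonomy, or with EMPTY when no emotion is expressed. Given
two groups of speakers — here `patient` and `control` — three families of
questions arise:

1. **Narrative complexity.** Do the groups differ in lexical diversity and
   in the length/structure of their narratives?
2. **Emotional vocabulary.** Which emotion categories dominate each group's
   word choice?
3. **Distinctive words.** Which individual word types are characteristically
   over- or under-used by one group?

`emonarr` implements this pipeline end to end, together with a synthetic
corpus generator that provides exact ground truth for every stage.

## Data model and tag dialect

On disk a corpus is a directory of UTF-8 text files (one per participant,
filename stem = participant id) plus a TSV metadata table. Tags are
line-initial markers following the grammar
`"++" EMOTION ( "(" CODE ("/" CODE)* ")" )? "++" ":"?`, case-insensitive in
the emotion name and tolerant of interior whitespace; the canonical form
written back out is `++EMOTION(C1/C2)++`. Narrative text runs from the tag
(or the remainder of the tag line after the colon) to the next tag line.
Text before the first tag, a tag with no following text, and tag/metadata
mismatches are hard errors: annotation bugs should fail loudly, not be
silently repaired. A narrative carries exactly one primary emotion;
multi-code tags attribute the narrative to each listed subcategory but to a
single primary.

EMPTY narratives are retained in the corpus — they count toward whole-corpus
token totals — but are excluded from every emotion-conditioned statistic,
mirroring how emotionless discourse is tagged yet never analysed as an
emotion.

## The taxonomy

The 21 subcategory codes roll up to the five primaries as 7 (HAPPY), 1
(ANGRY), 4 (SAD), 5 (FEAR) and 3 (DISGUST), with the dual code PC
("Surprise") resolving to HAPPY for positive lexicon entries and FEAR for
negative ones. Two deliberate quirks of the published table are kept
verbatim rather than "fixed": Grief is coded PF with *negative* polarity
under SAD despite the P-prefix convention, and PC is the only code whose
primary depends on polarity. Lexicon matching is exact surface-form
equality — no stemming or lemmatization — because the intended use is on
pre-segmented word tokens.

## Preprocessing

Sentence segmentation splits on a configurable terminator set (default
`。！？.!?`; the terminator run attaches to its sentence, and trailing text
without a terminator forms a final sentence). Tokenization is a pluggable
strategy registry: the bundled `whitespace` strategy splits on whitespace
and drops punctuation-only tokens, and an adapter function can pass through
the output of any external word segmenter for languages without overt word
boundaries. The test surface deliberately uses Latin-script synthetic
corpora with the whitespace strategy, keeping heavyweight, hard-to-reproduce
segmenters out of the loop.

Two token streams matter downstream: narrative-complexity features use
**unfiltered** tokens, while emotion-word frequencies use **stopword
filtered** tokens (one word per line, `#` comments). Keyness retains
stopwords by default — function words are often the strongest keys — with a
`stoplist` argument to exclude them.

## Narrative-complexity features and group comparison

Per participant, over the concatenation of their non-EMPTY narratives:
type-token ratio (distinct forms / tokens), mean word length (characters /
token), words per sentence, sentences per narrative and words per
narrative. One value per participant (not per narrative) is the unit of
analysis, so a two-group comparison on *n1 + n2* participants has close to
*n1 + n2 − 2* degrees of freedom.

Groups are compared with Welch's unequal-variance t-test (delegated to
`stats::t.test`), with the sign convention `t = mean(group1) −
mean(group2)` and default order `(patient, control)`; the order is an
explicit argument because published tables of this kind are not always
internally consistent about sign. Feature values are additionally min-max
normalized over the **pooled** sample of both groups; because that is a
shared affine transform, the raw and normalized rows of the comparison
table share `t`, `df` and `p` exactly (a per-group normalization would
break this identity, which is why pooling is the only defensible choice).
A normalized table whose means reverse the raw ordering is therefore
arithmetically impossible; the package treats such published rows as
typographical. P-values are reported uncorrected by default, with an
optional Bonferroni adjustment.

## Emotion-word frequency profiles

Counts of lexicon words per group, after stopword filtering, at three
levels: polarity, the 5 primaries, and the 21 subcategories. A token whose
surface form appears under several codes counts **once per code** at the
21-way level but **exactly once** at the aggregated levels, attributed via
its first-listed lexicon entry (deterministic given lexicon order). This
keeps conservation exact: per group, the primary-level counts, the
polarity-level counts and the once-per-token emotional total are all equal.
Both absolute counts and counts per 1,000 filtered tokens are emitted;
relative counts are what make unequal corpus sizes comparable, and they are
invariant under duplicating every participant of a group.

## Keyness: the two-cell log-likelihood ratio

For a word with frequency $O_1$ in a corpus of $N_1$ tokens and $O_2$ in
$N_2$ tokens, expected frequencies under a shared rate are
$E_i = N_i (O_1 + O_2) / (N_1 + N_2)$ and the statistic is

$$-2\ln\lambda = 2\sum_{i=1}^{2} O_i \ln\frac{O_i}{E_i},$$

with the $x \ln x \to 0$ convention for a zero observed cell. This is the
**two-cell** form summed over the two corpora only — deliberately not the
four-cell 2×2 G-statistic, which differs numerically (e.g. 52.5 vs 53.1 on
a typical high-count row) — because the two-cell form is the one used in
the corpus-linguistics keyness tradition and reproduces published keyword
tables. It is nonnegative, exactly zero iff $O_1/N_1 = O_2/N_2$, and
symmetric under swapping the corpora.

Significance uses the $\chi^2_1$ quantile at $1-\alpha$ with
$\alpha = 10^{-4}$, truncated to two decimals: 15.13 (the exact quantile is
15.1367; truncation reproduces the conventional published cutoff).
Words are signed `+`/`−` by which corpus has the higher relative frequency
and ranked by the statistic, ties broken by pooled frequency then
lexicographically. The default `min_freq = 5` on pooled frequency
suppresses unstable low-count keys; `min_freq = 1` admits singletons, which
published tables of this kind do include. Relative frequencies are stored
at full precision; two-decimal percentage formatting is display-only
(`--display` in the CLI).

## The synthetic generator

`generate_corpus()` produces a seeded two-group corpus with exact
bookkeeping (`synthetic_truth`): per-group token totals, per-code emission
counts, stopword and marker counts. Each token of a narrative generated
under emotion *e* is drawn from one categorical distribution: subcategory
code *c* with probability $p_{g,c}$ (then uniformly one of that code's
lexicon words), stopword with probability $q_g$, a marker word at its
configured rate when the narrative's emotion matches, otherwise a
background word from a Zipf($s$) vocabulary. Marker mass comes out of the
background remainder, so per-code counts are exactly
Binomial(non-EMPTY-narrative tokens, $p_{g,c}$) — this is what makes the
exact-binomial recovery test clean. Narrative counts per emotion are
Poisson; sentence and token counts are shifted Poisson (`1 + Pois`), so
every sentence has at least one token. The narrative's subcategory tag is
the modal emitted code compatible with its primary (falling back to the
primary's first code), and EMPTY narratives (default 5% of the narrative
rate) contain background/stopword tokens only, exercising the exclusion
path.

Vocabulary, lexicon and stoplist are disjoint pseudo-words built from
consonant-vowel syllables, word length 1 + Poisson(0.5) *syllables*. Two
limitations follow. First, with 26 Latin letters a distinct vocabulary
cannot reach the ~1.5-character mean word length of a Chinese-segmented
corpus, so the syllable count, not the character count, carries that
distribution (mean word length in characters is ~3). Second, the generator
has no topical coherence, no participant-level rate heterogeneity, and
oracle-perfect annotation — so passing recovery tests demonstrates that the
*statistics* behave as designed, not that the pipeline is robust to noisy
human annotation or discourse structure.

### The cohort preset

`cohort_preset()` fixes the generator at the shape of the motivating
two-group interview study, with every number taken from its published
summary tables: 34 patients vs 24 controls; expected token totals 167,795
vs 121,372; words per sentence 23.7 vs 19.5; sentences per narrative 2.41
vs 4.11 (narrative rates per emotion are derived from these so expected
token totals hit their targets); stopword probabilities 15.45% and 12.25%
from the raw vs function-word-removed corpus sizes; base per-code emission
0.002 with the patient rate doubled for NC, NE, NN, PA, PG, PB (the
reported fear/disgust/happiness inflation); and two 10×-ratio marker words
in SAD narratives, patient-side `isolation` (0.4% vs 0.04%) and
control-side `outbreak` (0.04% vs 0.4%). These values are the preset's
definition, not tuning knobs.

## Numerical and design choices

* Zero cells contribute zero to the keyness sum (the $x\ln x$ limit); the
  statistic is clamped at 0 against `-0`/rounding at exact proportionality.
* Threshold truncation (not rounding) of the $\chi^2_1$ quantile, matching
  the conventional 15.13.
* `welch_t` requires ≥ 2 values per group and nonzero variance in at least
  one; comparison-table rows that fail this are marked `computable = FALSE`
  rather than erroring, so one thin emotion stratum does not kill a report.
* Min-max normalization errors on constant input (undefined denominator).
* `"NA"` is a legal subcategory code (Angry); all delimited readers use
  `colClasses = "character"` with empty-string-only NA handling so it
  survives I/O.
* Participants with zero narratives are corpus-construction errors; the
  generator guarantees at least one non-EMPTY narrative per participant.
* Keyness candidate universe is every word type passing `min_freq` in the
  pooled streams; the published tables' candidate policy is not stated, so
  both `min_freq` and the threshold are configurable.

## Validation strategy and problem sizes

The test suite checks each stage against independent oracles: an
algebraically distinct evaluation of the keyness formula (agreement to
1e-9 on 1,000 random tables), first-principles sums for Welch's t,
published keyword rows recomputed from their printed frequencies (within
5%, the high-count and zero-cell rows within 0.5% and 1%), exact
round-trip identity of corpus I/O, and exact conservation of emotion
counts. Calibration and power use simulation at sizes chosen to balance
statistical resolution against run time: 100 seeds of a symmetric ~24k
token/group corpus for the null calibration of the 15.13 threshold
(average significant fraction ≤ 0.001), and 100 seeds of the full cohort
preset for recovery (marker words flagged and the two narrative-structure
contrasts significant at p < 0.01 in ≥ 95% of seeds; per-code frequencies
inside exact binomial 99% intervals in ≥ 97% of checks, 99% expected).

## Limitations

Bag-of-words throughout: negation scope is invisible, so words of fear
quoted inside a happy narrative ("death is *not dreadful*") count as fear
vocabulary. No annotation-noise model, no intensity weighting, no
length-corrected diversity indices (MATTR/MTLD), and no effect-size
measures for keyness beyond the statistic and relative frequencies.
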