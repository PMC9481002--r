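# emonarr

Text mining of **emotion-tagged interview narratives**: compare two groups
of speakers (e.g. patients vs healthy controls) on narrative complexity,
emotional vocabulary, and group-distinctive words.

Clinical interview transcripts are segmented by human coders into
*emotional narratives* — discourse units tagged `++EMOTION(SUBCODE)++` with
one of five primary emotions (HAPPY, SAD, ANGRY, FEAR, DISGUST, or EMPTY
for emotionless stretches) plus subcategory codes from a 21-way affect
taxonomy. `emonarr` parses this dialect, and provides three analyses plus a
validated synthetic-data generator:

1. **Narrative-complexity features** per participant (type-token ratio,
   mean word length, words/sentence, sentences/narrative, words/narrative),
   compared between groups with Welch's unequal-variance t-test on raw and
   pooled min-max-normalized values (a shared affine transform, so both
   variants share t and p).
2. **Emotion-word frequency profiles** against an affect lexicon
   (word → subcategory code → primary emotion → polarity), as conditional
   frequency distributions at the polarity, 5-emotion and 21-subcategory
   levels, in absolute counts and per 1,000 stopword-filtered tokens.
3. **Keyness**: word types over-/under-used by one group, ranked by the
   two-cell log-likelihood ratio

   &nbsp;&nbsp;&nbsp;&nbsp;−2 ln λ = 2 Σᵢ Oᵢ ln(Oᵢ/Eᵢ),&nbsp;&nbsp;
   Eᵢ = Nᵢ (O₁+O₂)/(N₁+N₂),&nbsp;&nbsp; i ∈ {1, 2},

   with the x ln x → 0 convention for zero cells and the conventional
   significance cutoff 15.13 (the χ²₁ quantile at 1 − 10⁻⁴, truncated to
   two decimals; df = 1, p < 0.0001).
4. **Synthetic corpora** with exact ground truth (`generate_corpus()`),
   including a study-shaped preset (`cohort_preset()`): 34 vs 24
   participants, ~168k vs ~121k tokens, group-specific sentence/narrative
   structure, patient-inflated emotion categories and injected marker
   words — so every pipeline stage is testable against known truth.

## Worked example

```r
library(emonarr)

gen <- generate_corpus(cohort_preset(), seed = 7)
gen$corpus
#> <emonarr_corpus> 58 participants (control 24, patient 34), 4435 narratives
#> narratives by emotion: HAPPY=862 SAD=850 ANGRY=841 FEAR=837 DISGUST=838 EMPTY=207

cmp <- feature_comparison_table(gen$corpus)  # t = patient - control
cmp$generic[cmp$generic$variant == "raw", c("feature","mean1","mean2","t","p")]
#>   feature                  mean1  mean2      t        p
#> 1 ttr                      0.179  0.183  -1.42 1.63e- 1
#> 2 mean_word_length         3.53   3.56   -6.00 1.96e- 7
#> 3 words_per_sentence      23.7   19.6    40.0  7.52e-43
#> 4 sentences_per_narrative  2.39   4.11  -30.1  4.30e-27
#> 5 words_per_narrative     56.7   80.6   -20.3  4.51e-23

ek <- emotion_keyness(gen$corpus, "SAD")
ek$table[1:3, c("word","ll","freq1","rel1","freq2","rel2","sign")]
#>   word         ll freq1   rel1 freq2   rel2 sign
#> 1 isolation 113.    144 0.464      8 0.0342 +
#> 2 outbreak   88.3    18 0.0580   100 0.427  -
#> 3 we         18.7    66 0.213     17 0.0727 +
```

Reading the output: the simulated patients pack more words into each
sentence (23.7 vs 19.6, t = 40 under the `t = patient − control`
convention) but produce fewer sentences and words per narrative — exactly
the structure the preset encodes. In the SAD-narrative keyness table the
injected marker `isolation` tops the patient side (LL = 113 ≫ 15.13, sign
`+`, relative frequencies 0.46% vs 0.03%) and `outbreak` the control side;
`we` is a background word that drifted over the threshold on this seed.
Real corpora are read with
`read_corpus("corpus_dir/", "metadata.tsv")`, lexicons with
`load_lexicon()` (a 42-word toy lexicon ships in `inst/extdata/`).

## Command line

```sh
./exec/emonarr simulate --out sim --seed 7                  # synthetic corpus + truth.json
./exec/emonarr report --corpus sim/corpus --metadata sim/metadata.tsv \
    --lexicon sim/lexicon.tsv --stoplist sim/stoplist.txt --out sim/reports
```

Subcommands `simulate`, `features`, `emofreq`, `keyness`, `report`; all
outputs are UTF-8 TSV, logs go to stderr, and identical inputs + seed give
byte-identical outputs.

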