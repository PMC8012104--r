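---
title: "Viewing-time decomposition and text-predictability modelling with readgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viewing-time decomposition and text-predictability modelling with readgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

readgaze implements a complete analysis chain for word-level reading-time
research: from raw fixation logs to linear mixed-effects models and path
analyses that relate viewing time to local word predictability and to
multi-scale semantic similarity of the text. Because raw developmental
eye-tracking corpora are rarely redistributable, the package pairs every
analysis stage with a seeded synthetic-study generator whose ground truth is
known exactly, so the whole chain is validated by parameter recovery rather
than by reference to a fixed dataset.

```{r setup}
library(readgaze)
```

## The viewing-time decomposition

The total time a reader spends on a word is partitioned into three additive
components, distinguished by *when* the time accrues relative to the eyes'
first pass over the word:

* **FFD** (first-fixation duration): the duration of the first fixation on
  the word, provided the eyes arrived by a forward (reading-order) saccade.
  Reflects early, local word processing.
* **RFD** (refixation duration): the summed durations of immediately
  subsequent fixations on the same word, before the eyes leave it. Reflects
  extended lexical processing.
* **RRD** (re-reading duration): all viewing time on the word after the eyes
  have left it once — regressions back into the word and later re-visits.
  Reflects integration difficulty.

Gaze duration is GD = FFD + RFD, and FFD + RFD + RRD equals the word's total
retained viewing time — exactly, in integer milliseconds. That conservation
identity holds by construction in `decompose_viewing_times()` and is asserted
over hundreds of simulated scanpaths in the test suite.

Two boundary rules needed a decision because standard verbal definitions do
not pin them down:

* A word whose *first* arrival is regressive (from a later word) has
  FFD = RFD = 0 and all its time in RRD. This keeps the "forward-saccade
  arrival" clause of the FFD definition literal: a first pass never starts
  with a regression, even if a forward arrival happens later.
* The trial-initial fixation counts as a forward arrival (there is no prior
  word to come from).

An independent event-replay oracle — a per-fixation state machine written
separately from the run-length implementation — reproduces the decomposition
exactly on every simulated scanpath in the tests.

## Pre-processing filters

`filter_fixations()` applies the conventional exclusions for connected-text
reading, in a fixed precedence order so that the exclusion report is
deterministic (each fixation is counted under the first rule it violates):

1. blink-contaminated fixations;
2. the first and last fixation of each trial;
3. line-switch fixations (the first fixation after a change of display
   line);
4. durations below 80 ms or above 800 ms — the bounds are strict, so 80 ms
   and 800 ms themselves are retained;
5. fixations on the first or last word of a display line;
6. landings exactly on a word boundary (assigned to neither neighbour);
7. anything that maps outside the text.

The `FilterReport` partitions the input exactly:
`n_input = n_retained + sum(exclusions)`. Re-filtering retained output is a
no-op: the output carries the original stream's predecessor-line and
trial-edge context as provenance columns, so the trial-edge and line-switch
rules do not re-trigger on data they have already seen.

Fixation-to-word mapping works in line-local character units: a fixation is
assigned to the word whose span *strictly* contains the landing position.
This is the AOI (area-of-interest) convention for unspaced scripts, where
word regions abut and a landing on the shared edge is genuinely ambiguous.

## Word predictability: frequency and surprisal

Word frequency is the natural-log relative unigram frequency
$\ln(c(w)/N)$ from a Google-style n-gram count table. Unseen words receive
the add-one floor $\ln\!\big(1/(N + V + 1)\big)$ (with $V$ the unigram
vocabulary size), which sits strictly below every seen word's value, so the
measure stays strictly increasing in count.

Surprisal is $-\ln P(w_i \mid \text{context})$ with the context limited to
the two preceding words of the same sentence (a trigram model; longer
contexts run into count sparsity). The conditional probability is the ratio
of the joint to the context count at the highest usable order, backing off
trigram → bigram → unigram. The backoff rule fires whenever the higher-order
estimate is *zero or undefined* — i.e. when either the context count or the
joint count is zero — so every query returns a finite value; at the unigram
level an unseen target falls back to the same add-one floor as the frequency
measure. The simpler rule "back off only on a zero context count" would
return infinity for an attested context followed by an unattested word,
which is useless as a regression covariate; this is the one place where the
package chooses the stricter of two readings of the standard recipe. For
seen words with empty context, surprisal and frequency are consistent by
construction: $s(w) = -\ln(c(w)/N)$.

Both measures use natural logarithms (nats) throughout. Sentence boundaries
block surprisal context: sentence-initial words are scored from a shorter or
empty context rather than conditioning across the boundary. Tokenization is
an *input* (a validated token table with character spans); the package does
not segment text itself.

All of this is verified against a brute-force oracle that recounts n-grams
directly from the raw token stream and applies the same stated rule, to
1e-12 nats on a 1,000-token corpus.

## Multi-scale semantic similarity

Four cosine-similarity measures locate each word in its discourse context,
computed from an embedding file (word2vec text format with
`word:`/`sent:`/`para:` keys; the encoder that produced the vectors is
deliberately outside the package, so the pipeline is deterministic and
download-free):

* `word_sent` — fixated word vs. its containing sentence;
* `sent_sent` — containing sentence vs. the preceding sentence;
* `sent_para` — containing sentence vs. its containing paragraph;
* `para_para` — containing paragraph vs. the preceding paragraph.

Sentence- and paragraph-level values are constant across the words of a
sentence (exactly — the same stored value is replicated, not recomputed).
Two conventions were open and are fixed as follows: the "preceding sentence"
follows document order across paragraph boundaries, so `sent_sent` is
defined for every non-initial sentence; and document-initial units emit
missing values (`NA`) rather than an imputed similarity — those rows are
excluded from models and counted.

## The mixed-effects model

The modelling unit is one word-viewing instance: one (participant, word)
pair with a positive component duration. Each component (FFD, RFD, RRD) is
modelled on the raw millisecond scale with seven fixed predictors — log
frequency, surprisal, the four similarities, and reading ability — and
crossed random intercepts for participant and word:

```
dv ~ freq + surprisal + word_sent + sent_sent + sent_para + para_para +
     ability_code + (1 | participant_id) + (1 | token_id)
```

Estimation is REML via lme4. Ability is an ordered three-level factor
(poor < average < good) coded numerically −1/0/1, which makes the main
effect a per-level slope and keeps optional ability × similarity
interactions interpretable. Covariates are z-scored across the modelled rows
by default, so estimates are in ms per SD. p-values use Satterthwaite
degrees of freedom (lmerTest) for final fits; simulation loops use the
residual-df approximation (`df_method = "residual"`), which is
indistinguishable at these sample sizes and an order of magnitude faster.
Non-convergence is flagged on the result, not thrown; singular fits (variance
components at the boundary) are legitimate and reported as such — in the
boundary case the fixed estimates coincide with OLS, which the tests assert
to 1e-6. No multiple-testing correction is applied anywhere, and the report
metadata says so.

## Recursive path analysis

To unpack how the similarity measures influence viewing time directly versus
through each other, the package fits a causally ordered system of per-equation
OLS regressions on standardized variables, coarse to fine:

```
para_para -> sent_para -> sent_sent -> word_sent -> DV
```

with frequency and surprisal as exogenous covariates in every equation. Each
endogenous variable is regressed on all its predecessors; the direct effect
of a variable on the DV is its coefficient in the DV equation, the indirect
effect is the sum over all directed paths of products of path coefficients,
and total = direct + indirect holds to numerical precision (asserted at
1e-10). With a single endogenous variable the system reduces to one OLS
regression, which the tests check coefficient-by-coefficient against the
normal equations solved by hand. The coarse-to-fine ordering mirrors the
hierarchy of the measures themselves (a paragraph's relation to the previous
paragraph is upstream of any sentence-level relation); a covariance-based
SEM estimator would be an alternative, but for a recursive system of
observed variables the equation-by-equation least-squares solution is
identical in the population and simpler to audit. RFD is excluded from path
analysis (refixations are scarce once durations are decomposed, and nearly
homogeneous word lengths make RFD unstable); FFD and RRD are analysed,
overall and within good/poor ability groups.

## What the synthetic generator emulates — and what it does not

`generator_config()` fixes the study conditions; all stages are deterministic
given its `seed`. The defaults describe a primary-school connected-text
reading study:

* **Participants**: 20 poor / 20 average / 19 good readers per grade, grades
  4 and 5 (59 per grade).
* **Text**: paragraphs of 5–7 sentences, words of 1–5 characters drawn from
  a Zipf-distributed vocabulary (exponent 1, 500 types), laid out on wrapped
  display lines of 20 characters; one trial per paragraph.
* **Embeddings**: 128-dimensional unit vectors on a topic chain — a
  paragraph starts a new topic with probability 0.3, sentence vectors
  concentrate around their paragraph vector and word vectors around their
  sentence. The concentration parameters are 1/SD of the added noise: `Inf`
  copies the parent exactly (so sent–para cosine is 1), `0` gives an
  unrelated random direction (expected cosine 0 at dimension 128).
* **Durations**: the latent first-fixation level is
  η = β₀ + Xβ + β_a·ability + u_participant + u_word in milliseconds, with X
  the standardized predictors; the realized duration adds centred lognormal
  noise (SD 50 ms, shape 0.6) and is rounded to integer ms. The default β
  (intercept 250; freq −15; surprisal +10; similarities −8/−6/−5/−4; ability
  −10 ms per level; random SDs 40/25 ms) gives means near 250 ms and
  right-skewed spreads typical of children's first-fixation data. The
  millisecond-scale linear predictor (rather than a log-scale one) is a
  deliberate choice: it is the scale on which the mixed models operate, so
  injected effects are recoverable in their own units, while the lognormal
  noise term preserves the positivity and right skew of empirical duration
  distributions.
* **Scanpaths**: words are skipped with probability 0.1, refixated with 0.15,
  and re-visited with 0.15. Re-visits are replayed from the end of the trial
  backwards so each re-visit arrival is a genuine regression. Contaminants
  (blinks, out-of-range durations, boundary landings) are opt-in at
  configurable rates and are injected as *extra* events, so the filter's
  per-reason counts remain predictable from the configuration.

The generator is deliberately not a cognitive model: no saccade-landing
distributions, no parafoveal preview, no skipping that depends on word
length or frequency, no spillover. Passing recovery tests therefore shows
that the *pipeline* is unbiased and correctly wired under the assumed
generative model — not that the model is true of children's reading. Effects
estimated from real data still depend on the usual identification
assumptions (no unmodelled confounding between the text measures, correct
random-effects structure).

## Numerical and reproducibility choices

* Character spans are 0-based, half-open; all ids (tokens, sentences,
  paragraphs, lines) are 0-based integers.
* Cosines are clamped to [−1, 1] against floating-point round-off; zero
  vectors and dimension mismatches are errors, not silent NA.
* Durations are integer milliseconds end to end, which is what makes the
  conservation identity exact rather than approximate.
* Every stage re-seeds from `config$seed` plus a fixed small offset, so
  stages can be re-run independently and whole runs are byte-identical.
  Manifest timestamps are off by default for that reason
  (`record_timestamp = TRUE` opts in and breaks byte-level identity).
* Sub-analyses that cannot be fitted (a grade with no observations, a
  degenerate subset) are recorded as failure markers in the report bundle;
  the rest of the grid still runs.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at sizes chosen to make
Monte-Carlo noise small relative to the tolerances: conservation and oracle
equivalence on 510 scanpaths (30 participants × 17 paragraphs); the
surprisal oracle on a 1,000-token corpus; LMM recovery on 100 replicates of
60 participants × 400 words (2-SE interval coverage per fixed effect, near
the nominal 95%); the type-I error of the null model on 300–500 replicates
of 40 participants × 120 words (rejection rate ≈ 5%); and the mediation
chain pp →(0.5)→ sp →(0.4)→ DV at n = 5,000, whose indirect effect 0.20 is
recovered within ±0.03.

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1,
                        n_per_group = c(poor = 5, average = 5, good = 5),
                        n_paragraphs = 8, embedding_dim = 32)
manifest <- run_pipeline(cfg, "study-out")

# per-word measures and the filter's accounting
measures <- read.delim("study-out/measures.tsv")
report <- jsonlite::read_json("study-out/filter_report.json")

# one fitted table from the analysis grid
bundle <- jsonlite::read_json("study-out/report/bundle.json")
bundle$lmm$FFD$overall$coefficients
```

## Known limitations

* The filter's provenance columns make re-filtering idempotent, but mixing
  filtered and unfiltered rows in one data frame is not supported.
* `decompose_viewing_times()` emits skipped words under the
  trial-per-paragraph convention (`trial_id == paragraph_id`); other trial
  layouts still decompose fixated words correctly but cannot infer which
  unfixated words belonged to the trial.
* The path analysis is a recursive system over observed variables; it does
  not model latent constructs or correlated errors between equations.
* Surprisal and frequency come from raw count tables; no smoothing beyond
  the documented add-one floor and backoff is implemented.
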