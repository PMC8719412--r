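# dictagger

Dictionary-augmented multi-task BiLSTM-CRF tagging for clinical named entity
recognition (NER) in R.

Clinical records are dense with entity mentions — symptoms, drugs, anatomy,
operations, exams — but annotated clinical text is scarce, and purely
data-driven taggers fail on entities that are rare or absent in training
data. `dictagger` addresses this by injecting external knowledge into a
character-level neural sequence tagger:

* **Gazetteer n-gram features.** Around each character `x_i`, ten text
  fragments are formed (for each n in 2..6, the n-gram ending at `x_i` and
  the n-gram starting at `x_i`). Each fragment is looked up in an entity
  dictionary by exact match; a hit contributes the 3-bit code of the matched
  entity type (e.g. drug = `(0,0,1)`), a miss contributes `(0,0,0)`. The ten
  codes concatenate into a 30-dimensional binary vector that carries both
  entity-type and boundary information — and it fires equally for entities
  the training data never showed.
* **Radical features.** Chinese characters share sub-character components
  (radicals) with semantic content (anatomy terms tend to carry the "meat"
  radical); each character also receives a learned radical embedding.
* **A multi-task network.** The concatenated features
  `[char embedding ; radical embedding ; dictionary vector]` feed a shared
  bidirectional LSTM. Two heads consume the shared encoding in parallel:
  an auxiliary *named entity segmentation* head (is this character inside
  any entity?) trained with sigmoid + cross-entropy (`loss1`), and the
  primary *recognition* head, a linear-chain CRF over BIO labels trained by
  negative log-likelihood (`loss2`). The joint objective is

  ```
  L = alpha * loss1 + beta * loss2        (default alpha : beta = 2 : 3)
  ```

  Prediction uses only the CRF head, decoded with Viterbi.

The whole stack — LSTM cell, masked batched backpropagation through time,
CRF forward algorithm and forward-backward gradients, Viterbi, Adam — is
implemented in base R matrix code and verified against enumeration oracles
and finite-difference gradient checks in the test suite.

A synthetic-data module generates dictionaries, radical tables and tagged
corpora with controlled entity rarity and dictionary coverage, so every
experiment below runs hermetically with no external data.

## Worked example

```r
library(dictagger)

spec <- synth_spec(seed = 1)      # 200 train / 60 test sentences, 5 types
syn  <- gen_synthetic(spec)
syn$train
#> <ner_corpus> 200 sentences, 3640 characters, 302 entity mentions
#>   types: Type1, Type2, Type3, Type4, Type5

cfg <- train_config(batch_size = 32, epochs = 30, learning_rate = 0.01,
                    char_dim = 16, radical_dim = 8, hidden_size = 24,
                    dropout = 0.2, seed = 42)
model <- train_tagger(syn$train, syn$dict, syn$scheme, syn$radicals, cfg)
model
#> <dictagger_model> 5 types, 11 labels | char 16 + radical 8 + dict 30 -> BiLSTM 24x2 | dictionary on
#>   trained 30 epochs; final loss 0.0875

pred   <- predict_corpus(model, syn$test)
entity_prf(syn$test, pred)
#> <eval_report> P 100.00%  R 100.00%  F 100.00%  (TP 98, FP 0, FN 0)

stratified_rare_recall(occurrence_counts(syn$train), syn$test, pred)
#>   bucket recall tp support
#> 0      0      1 11      11
#> 1      1      1 12      12
#> 2      2      1  3       3
#> 3      3      1  9       9
```

`entity_prf` scores strict span matches: a prediction counts only when its
`(type, start, end)` triple equals a gold mention. The rare-entity report
buckets each test mention by how often its `(surface, type)` occurred in
training (0 = unseen, 1-3 = rare; more frequent mentions are excluded) and
reports recall per bucket — the regime where dictionary features matter most.
Here the gazetteer covers every surface, so even the 11 never-seen test
mentions are all recovered.

## Command-line interface

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/dictagger.R gen-synthetic   --out data/ --seed 3
Rscript inst/cli/dictagger.R encode-features --corpus data/train.conll \
    --dict data/dictionary.tsv --out data/features.txt
Rscript inst/cli/dictagger.R train    --corpus data/train.conll --dict data/dictionary.tsv \
    --radicals data/radicals.tsv --out model.rds
Rscript inst/cli/dictagger.R predict  --model model.rds --input data/test.conll --out pred.conll
Rscript inst/cli/dictagger.R evaluate --gold data/test.conll --pred pred.conll \
    --train data/train.conll --out report.json
```

Corpora are two-column CoNLL-style text (`<char>TAB<tag>`, blank line
between sentences; a third column carries predictions), dictionaries and
radical tables are two-column TSV.

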