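# emomine

Dictionary-based emotion analysis of cancer-related social-media posts:
lexicon coding, Apriori association rules, and co-occurrence networks.

## The problem

Cancer survivors and the people around them post about their emotions on
blogs, online communities ("cafés"), Twitter, and message boards. Mining
those posts reveals which disease factors — cancer type, stage,
treatment, survivorship phase, symptoms, demographics — travel together
with which emotions, information that can guide tailored emotional
support programs. `emomine` implements that analysis as a tested,
reusable pipeline for anyone working with keyword-coded health posts:

1. **Lexicon coding.** An ontology-derived lexicon maps consumer terms
   (including colloquial and bilingual synonyms) to 47 analysis items:
   4 multi-label **emotion groups** — hope/gratitude (HG),
   fear/anxiety/overwhelmed (FAO), sadness/depression/loneliness/guilt
   (SDLG), anger/denial (AD), aggregating nine ontology emotion classes —
   and 43 **emotion-related factor groups** (gender 2, age bands 9,
   cancer types 14, stages 3, treatments 6, survival stages 3, symptom
   clusters 6). Posts pass an inclusion/exclusion funnel (cancer topic,
   ≥1 emotion term, no stop keywords, no advertising keywords) and are
   coded 0/1 per item with count-once semantics.
2. **Association rules.** Apriori frequent-itemset mining over the
   post × item matrix, then factor → emotion rules with

   - support(A ⇒ e) = P(A ∪ {e}),
   - confidence = P(A ∪ {e}) / P(A),
   - lift = confidence / P(e),

   where lift > 1 indicates positive association. Top-k rules per
   emotion group are ranked by lift.
3. **Co-occurrence networks.** Per length stratum (long-form =
   blogs + cafés + boards; Twitter, capped at 140 characters), items are
   nodes with frequency (posts mentioning the item) and degree (distinct
   co-mentioned items); undirected edges are weighted by co-mention post
   counts. Exported as GraphML and edge-list CSV.
4. **Synthetic corpus generator.** Because real corpora of this kind are
   not redistributable, the package generates channel-tagged posts with
   known factor prevalences and a logistic factor → emotion effect
   model, plus an exact enumeration oracle `expected_lift()`. Every
   downstream stage is validated against planted ground truth.

## Worked example

```r
library(emomine)

cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "emomine"))
cfg$out_dir <- tempfile("emomine_demo")
res <- run_pipeline(cfg)
res$emotion_frequencies
#>   emotion_group count percent
#> 1            HG  1862    46.6
#> 2           FAO  1833    45.8
#> 3          SDLG  1534    38.4
#> 4            AD   346     8.6
head(res$top_rules, 3)
#> 3 association rules
#>   {breast_cancer, chemotherapy} => {HG}  supp 0.013 conf 0.810 lift 1.739
#>   {female, radiation_therapy} => {HG}  supp 0.013 conf 0.769 lift 1.652
#>   {acute_survival, radiation_therapy} => {HG}  supp 0.033 conf 0.749 lift 1.608
head(top_nodes(res$networks$twitter), 3)
#>             item frequency percent degree
#> 1 acute_survival       356    46.8     42
#> 2             HG       353    46.4     42
#> 3            FAO       331    43.6     44
```

The demo generates 4,000 synthetic posts under the default study-like
conditions (channel shares ≈ 40/39/19/2%, emotion marginals calibrated
to 46.5/45.2/39.4/8.0%), so hope/gratitude tops the emotion table,
treatment/acute-survival antecedents dominate the hope/gratitude rules,
and the acute-survival and emotion nodes dominate the networks — the
qualitative structure reported for the real 321,339-post corpus.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/emomine-pipeline.R --config inst/extdata/demo_config.yaml \
    --out-dir demo_out --seed 20200930
```

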