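# Default pipeline configuration. Band cut points (low 0-2, medium 3-4,
# high 5-7) are fixed in the scoring module and are not configurable here.
min_words: 300          # minimum words per page
dedup_threshold: 0.8    # word 5-shingle Jaccard at/above which pages are duplicates
folds: 10               # cross-validation folds
seed: 42
alpha: 0.05             # significance level for term ranking
min_shared_pages: 2     # network inclusion threshold
simulate: false
svm:                    # margin-based family
  cost: 100
  gamma: 1
  kernel: linear
rf:                     # tree-ensemble family
  ntree: 10
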