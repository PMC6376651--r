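# Packaged demonstration configuration: synthetic cohort end-to-end run.
seed: 20190214
outdir: phenorich_demo
synthetic: true
thresholds:
  support: mean
  confidence: mean
ci_level: 0.95
min_weight: 0
gold_threshold: 0
top_k: 15
rare_only: false
query: rare_disease_01
overlap:
  n_kb_only: 60
  n_shared: 12
  n_literature_total: 200
  fraction_literature_explained_by_kb: 0.10
  fraction_literature_explained_by_emr: 0.12
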