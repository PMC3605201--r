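{
  "description": "Obesity benchmark match-scoring counts: candidate records, matches against the curated biomarker base, missed known biomarkers, SME-judged new testable hypotheses, and pathway-map confirmations.",
  "total": 2551,
  "benchmark_matches": 182,
  "missed": 308,
  "testable": 512,
  "pathway_confirmed": 71
}
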