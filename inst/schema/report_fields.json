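{
  "top_level": ["mode", "seed", "params", "stages"],
  "stages": {
    "diffexpr": ["n_genes", "n_up", "n_down"],
    "enrich": ["n_pathways", "n_significant", "top_pathway"],
    "prioritize": ["n_scored", "top_gene"],
    "network": ["n_nodes", "n_edges", "avg_degree", "avg_clustering", "top_hubs"],
    "metabolomics": ["n_features", "n_selected"],
    "dockrank": ["n_records", "n_profiled", "multi_target", "assay_candidates"],
    "doseresponse": ["compounds", "ic50_uM", "r2"]
  }
}
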