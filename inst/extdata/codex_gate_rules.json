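{
  "pass1": [
    {"phenotype": "Treg",
     "all": [{"marker": "FOXP3", "op": ">", "value": 1.4},
             {"marker": "CD4", "op": ">", "value": 1.1}]},
    {"phenotype": "CD8 T cell",
     "all": [{"marker": "CD8", "op": ">", "value": 1.4},
             {"marker": "CD3e", "op": ">", "value": 1.0}]},
    {"phenotype": "CD4 T cell",
     "all": [{"marker": "CD4", "op": ">", "value": 1.1},
             {"marker": "CD3e", "op": ">", "value": 1.1},
             {"marker": "CD8", "op": "<", "value": 1.4}]},
    {"phenotype": "NK cell",
     "all": [{"marker": "NKG2A", "op": ">", "value": 1.1},
             {"marker": "CD3e", "op": "<", "value": 1.1}]},
    {"phenotype": "Macrophage",
     "all": [{"marker": "CD20", "op": "<", "value": 1.5}],
     "any": [{"marker": "CD14", "op": ">", "value": 1.4},
             {"marker": "CD163", "op": ">", "value": 1.4},
             {"marker": "CD68", "op": ">", "value": 1.4},
             {"marker": "CD16a", "op": ">", "value": 1.4}]},
    {"phenotype": "CD4 T cell",
     "all": [{"marker": "CD4", "op": ">", "value": 1.1}]},
    {"phenotype": "B cell",
     "all": [{"marker": "CD20", "op": ">", "value": 1.5}]},
    {"phenotype": "Tumor",
     "any": [{"marker": "TP63", "op": ">", "value": 1.0},
             {"marker": "PanCK", "op": ">", "value": 1.0}]}
  ],
  "pass2": {
    "applies_to": ["CD8 T cell", "CD4 T cell", "Treg", "B cell", "NK cell"],
    "rules": [
      {"phenotype": "Treg",
       "all": [{"marker": "FOXP3", "op": ">", "value": 1.4}]},
      {"phenotype": "NK cell",
       "all": [{"marker": "NKG2A", "op": ">", "value": 1.1},
               {"marker": "CD3e", "op": "<", "value": 1.1},
               {"marker": "CD8", "op": "<", "value": 1.4}]},
      {"phenotype": "CD8 T cell",
       "all": [{"marker": "CD8", "op": ">", "value": 1.4},
               {"marker": "CD3e", "op": ">", "value": 0.9}],
       "ratio": {"num": "CD8", "den": "CD4", "op": ">", "value": 1.5},
       "any": [{"marker": "GZMK", "op": ">", "value": 1.1},
               {"marker": "GZMB", "op": ">", "value": 1.1},
               {"marker": "TCF1", "op": ">", "value": 0.9},
               {"marker": "PD1", "op": ">", "value": 0.9},
               {"marker": "CD8", "op": ">", "value": 2.0}]},
      {"phenotype": "CD4 T cell",
       "all": [{"marker": "CD4", "op": ">", "value": 1.1},
               {"marker": "CD3e", "op": ">", "value": 0.9}],
       "ratio": {"num": "CD8", "den": "CD4", "op": "<", "value": 1.5},
       "any": [{"marker": "PD1", "op": ">", "value": 0.9},
               {"marker": "TOX", "op": ">", "value": 0.9},
               {"marker": "TCF1", "op": ">", "value": 0.9}]},
      {"phenotype": "B cell",
       "all": [{"marker": "CD20", "op": ">", "value": 1.5}]}
    ]
  },
  "fallback": ["Macrophage", "Tumor"],
  "else_label": "Stroma"
}
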