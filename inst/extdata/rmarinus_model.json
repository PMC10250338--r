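{
  "species_id": "Rmar",
  "seed": 1,
  "gc_constant": 0.6,
  "constant_templates": [
    {
      "id": "grpMain",
      "length": 1100,
      "repeat_regions": [
        {"region_id": "C", "unit_len": 33, "min_units": 1, "max_units": 3, "tandem": false},
        {"region_id": "D", "unit_len": 21, "min_units": 1, "max_units": 4, "tandem": true},
        {"region_id": "E", "unit_len": 12, "min_units": 2, "max_units": 6, "tandem": true}
      ]
    },
    {
      "id": "grpAtp6",
      "length": 950,
      "repeat_regions": [
        {"region_id": "A", "unit_len": 30, "min_units": 1, "max_units": 3, "tandem": true}
      ]
    },
    {
      "id": "grpLSU",
      "length": 1000,
      "repeat_regions": [
        {"region_id": "B", "unit_len": 24, "min_units": 1, "max_units": 4, "tandem": true}
      ]
    }
  ],
  "genes": [
    {"name": "atp6",   "cds_len": 780,  "ncr_len": 260, "gc": 0.52},
    {"name": "atp9",   "cds_len": 234,  "ncr_len": 450, "gc": 0.50},
    {"name": "cob",    "cds_len": 1149, "ncr_len": 300, "gc": 0.50},
    {"name": "cox1",   "cds_len": 1590, "ncr_len": 300, "gc": 0.53},
    {"name": "cox2",   "cds_len": 750,  "ncr_len": 300, "gc": 0.52},
    {"name": "cox3",   "cds_len": 810,  "ncr_len": 300, "gc": 0.51},
    {"name": "nad1",   "cds_len": 978,  "ncr_len": 300, "gc": 0.49},
    {"name": "nad2",   "cds_len": 1482, "ncr_len": 300, "gc": 0.50},
    {"name": "nad4",   "cds_len": 1485, "ncr_len": 300, "gc": 0.51},
    {"name": "nad5_f", "cds_len": 1002, "ncr_len": 300, "gc": 0.50},
    {"name": "nad5_s", "cds_len": 999,  "ncr_len": 300, "gc": 0.49},
    {"name": "SSU",    "cds_len": 1497, "ncr_len": 300, "gc": 0.48},
    {"name": "LSU",    "cds_len": 2799, "ncr_len": 260, "gc": 0.50}
  ],
  "circle_plan": [
    {"gene": "atp6",   "template": "grpAtp6", "units": {"A": 2}},
    {"gene": "atp9",   "template": "grpMain", "units": {"C": 1}},
    {"gene": "cob",    "template": "grpMain", "units": {"C": 1}},
    {"gene": "cox1",   "template": "grpMain", "units": {"C": 3}},
    {"gene": "cox2",   "template": "grpMain", "units": {"C": 3}},
    {"gene": "cox3",   "template": "grpMain", "units": {"C": 1}},
    {"gene": "nad1",   "template": "grpMain", "units": {"C": 1}},
    {"gene": "nad2",   "template": "grpMain", "units": {"C": 1}},
    {"gene": "nad4",   "template": "grpMain", "units": {"C": 1}},
    {"gene": "nad5_f", "template": "grpMain", "units": {"C": 1}},
    {"gene": "nad5_s", "template": "grpMain", "units": {"C": 2}},
    {"gene": "SSU",    "template": "grpMain", "units": {"C": 1}},
    {"gene": "LSU",    "template": "grpLSU",  "units": {"B": 2}}
  ]
}
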