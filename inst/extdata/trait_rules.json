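{
  "note": "Rule-based metabolic trait classification for genome bins. A rule fires when all of its clauses are satisfied; a clause is satisfied when any of its listed features is present in the bin (namespace 'ko', 'pfam', 'symbol', 'rubisco_form', 'domain') or, for 'transporters', when the bin's organic-compound transporter gene count reaches 'min'. Gene symbols resolve through the editable symbol_map.",
  "symbol_map": {
    "nifH": "K02588", "nifD": "K02586", "nifK": "K02591",
    "hao": "K10535", "coxL": "K03520", "hoxH": "K00436",
    "prkA": "K00855", "rbcL": "K01601", "rbcS": "K01602",
    "soxA": "K17222", "soxX": "K17223", "soxB": "K17224",
    "soxC": "K17225", "soxY": "K17226", "soxZ": "K17227",
    "amoA": "K10944", "abfD": "K14534"
  },
  "rules": [
    {"label": "NCD",
     "clauses": [
       {"namespace": "symbol", "any_of": ["nifH"]},
       {"namespace": "symbol", "any_of": ["nifD"]},
       {"namespace": "symbol", "any_of": ["nifK"]}
     ]},
    {"label": "AOA",
     "clauses": [
       {"namespace": "domain", "any_of": ["archaea"]},
       {"namespace": "pfam", "any_of": ["PF12942"]},
       {"namespace": "symbol", "any_of": ["abfD"]}
     ]},
    {"label": "AOB",
     "clauses": [
       {"namespace": "domain", "any_of": ["bacteria"]},
       {"namespace": "symbol", "any_of": ["amoA"]},
       {"namespace": "symbol", "any_of": ["hao"]}
     ]},
    {"label": "NOB",
     "clauses": [
       {"namespace": "ko", "any_of": ["K00370"]},
       {"namespace": "ko", "any_of": ["K00371"]}
     ]},
    {"label": "SOB",
     "clauses": [
       {"namespace": "symbol", "any_of": ["soxB", "soxY", "soxA"]}
     ]},
    {"label": "CO-oxidizer",
     "clauses": [
       {"namespace": "symbol", "any_of": ["coxL"]}
     ]},
    {"label": "H2-oxidizer",
     "clauses": [
       {"namespace": "symbol", "any_of": ["hoxH"]}
     ]},
    {"label": "CBB-autotroph",
     "clauses": [
       {"namespace": "rubisco_form", "any_of": ["I", "II"]},
       {"namespace": "symbol", "any_of": ["prkA"]}
     ]},
    {"label": "mixotroph-candidate",
     "clauses": [
       {"namespace": "rubisco_form", "any_of": ["I", "II"]},
       {"namespace": "symbol", "any_of": ["prkA"]},
       {"namespace": "transporters", "min": 4}
     ]}
  ]
}
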