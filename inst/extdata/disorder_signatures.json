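{
  "signatures": [
    {
      "code": "ADSL",
      "name": "Adenylosuccinate lyase deficiency",
      "required_high": ["SAICAr", "Succinyladenosine"],
      "optional_high": [],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "ATIC",
      "name": "AICAR transformylase/IMP cyclohydrolase deficiency",
      "required_high": ["AICAr"],
      "optional_high": [],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "APRT",
      "name": "Adenine phosphoribosyltransferase deficiency",
      "required_high": ["Adenine", "2,8-Dihydroxyadenine"],
      "optional_high": [],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "HGPRT",
      "name": "Hypoxanthine-guanine phosphoribosyltransferase deficiency",
      "required_high": ["Hypoxanthine"],
      "optional_high": ["Xanthine"],
      "required_low": [],
      "confound_notes": "Orotidine elevation under allopurinol therapy is treatment-related, not pathognomonic."
    },
    {
      "code": "UPB1",
      "name": "Beta-ureidopropionase deficiency",
      "required_high": ["Beta-Ureidoisobutyric acid", "Beta-Ureidopropionic acid"],
      "optional_high": ["Dihydrouracil", "Dihydrothymine"],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "UMPS",
      "name": "Uridine monophosphate synthetase deficiency",
      "required_high": ["Orotic acid", "Orotidine"],
      "optional_high": [],
      "required_low": [],
      "confound_notes": "Allopurinol therapy elevates orotidine and orotic acid; not supportive when allopurinol is detected."
    },
    {
      "code": "DPD",
      "name": "Dihydropyrimidine dehydrogenase deficiency",
      "required_high": ["Uracil", "Thymine"],
      "optional_high": [],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "DHP",
      "name": "Dihydropyrimidinase deficiency",
      "required_high": ["Dihydrouracil", "Dihydrothymine"],
      "optional_high": ["Uracil", "Thymine"],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "TP",
      "name": "Thymidine phosphorylase deficiency",
      "required_high": ["Thymidine", "Deoxyuridine"],
      "optional_high": [],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "MoCoD",
      "name": "Molybdenum cofactor deficiency",
      "required_high": ["Xanthine"],
      "optional_high": ["Hypoxanthine"],
      "required_low": [],
      "confound_notes": "Indistinguishable from isolated XDH deficiency on this panel; sulfite markers needed for confirmation."
    },
    {
      "code": "ADA",
      "name": "Adenosine deaminase deficiency",
      "required_high": ["Deoxyadenosine"],
      "optional_high": ["Adenosine"],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "PNP",
      "name": "Purine nucleoside phosphorylase deficiency",
      "required_high": ["Inosine", "Guanosine"],
      "optional_high": ["Deoxyinosine", "Deoxyguanosine"],
      "required_low": [],
      "confound_notes": ""
    },
    {
      "code": "XDH",
      "name": "Xanthine dehydrogenase deficiency (hereditary xanthinuria)",
      "required_high": ["Xanthine"],
      "optional_high": ["Hypoxanthine"],
      "required_low": [],
      "confound_notes": "Indistinguishable from MoCoD on this panel."
    },
    {
      "code": "PRPPS",
      "name": "Phosphoribosylpyrophosphate synthetase superactivity",
      "required_high": ["Hypoxanthine", "Xanthine"],
      "optional_high": [],
      "required_low": [],
      "confound_notes": ""
    }
  ]
}
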