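{
  "Female": {"gender": "Female"},
  "Male": {"gender": "Male"},
  "Fetus": {"age_category": "Fetus"},
  "Infant, Newborn": {"age_category": "Newborn"},
  "Infant": {"age_category": "Infant"},
  "Child, Preschool": {"age_category": "Preschool"},
  "Child": {"age_category": "Child"},
  "Adolescent": {"age_category": "Adolescent"},
  "Young Adult": {"age_category": "Young"},
  "Adult": {"age_category": "Adult"},
  "Middle Aged": {"age_category": "Middle age"},
  "Aged": {"age_category": "Aged"},
  "Aged, 80 and over": {"age_category": "Aged 80"}
}
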