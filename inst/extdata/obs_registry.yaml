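- name: d_fiber
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_carotene
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_riboflavin
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_niacin
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_vitamin_b6
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_total_folate
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_vitamin_b12
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_vitamin_c
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_vitamin_e
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_calcium
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_magnesium
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_zinc
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_copper
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_selenium
  class: dietary
  direction: antioxidant
  scoring: tertile
- name: d_total_fat
  class: dietary
  direction: prooxidant
  scoring: tertile
- name: d_iron
  class: dietary
  direction: prooxidant
  scoring: tertile
- name: met_score
  class: lifestyle
  direction: antioxidant
  scoring: tertile
- name: cotinine
  class: lifestyle
  direction: prooxidant
  scoring: tertile
- name: bmi
  class: lifestyle
  direction: prooxidant
  scoring: tertile
- name: alcohol_g_day
  class: lifestyle
  direction: prooxidant
  scoring: alcohol_category
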