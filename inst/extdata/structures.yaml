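structures:
- name: liver
  id: 1
  category: I
  A: 95.0
  B: 160.0
  kappa_si: 0.96
  kappa_ap: 0.916666666667
- name: gallbladder
  id: 2
  category: I
  A: 82.0
  B: 160.0
  kappa_si: 0.96
  kappa_ap: 0.916666666667
- name: pancreas
  id: 3
  category: I
  A: 100.0
  B: 112.0
  kappa_si: 0.7
  kappa_ap: 0.7
- name: spleen
  id: 4
  category: I
  A: 25.0
  B: 170.0
  kappa_si: 0.85
  kappa_ap: 0.85
- name: stomach
  id: 5
  category: I
  A: 85.0
  B: 140.0
  kappa_si: 0.8
  kappa_ap: 0.8
- name: kidneys
  id: 6
  category: I
  A: 90.0
  B: 105.0
  kappa_si: 0.6
  kappa_ap: 0.6
- name: heart
  id: 7
  category: I
  A: 45.0
  B: 150.0
  kappa_si: 0.55
  kappa_ap: 0.1
- name: myocardium
  id: 8
  category: I
  A: 65.0
  B: 150.0
  kappa_si: 0.55
  kappa_ap: 0.1
- name: heart_blood
  id: 9
  category: I
  A: 110.0
  B: 150.0
  kappa_si: 0.55
  kappa_ap: 0.1
- name: muscle
  id: 10
  category: II
  A: 40.0
  B: 140.0
  kappa_si: 0.1
  kappa_ap: 0.1
- name: body
  id: 11
  category: II
  A: 30.0
  B: 80.0
  kappa_si: 0.1
  kappa_ap: 0.1
- name: static_marrow
  id: 12
  category: II
  A: 30.0
  B: 80.0
  kappa_si: 0.0
  kappa_ap: 0.0
- name: intestine_wall
  id: 13
  category: II
  A: 30.0
  B: 85.0
  kappa_si: 0.55
  kappa_ap: 0.55
- name: lungs
  id: 14
  category: III
  A: 18.0
  kappa_si: 0.5
  kappa_ap: 0.5
- name: airway_tree
  id: 15
  category: III
  A: 235.0
  kappa_si: 0.3
  kappa_ap: 0.3
- name: intestine_air
  id: 16
  category: III
  A: 40.0
  kappa_si: 0.55
  kappa_ap: 0.55
- name: esophagus_wall
  id: 17
  category: III
  A: 136.0
  kappa_si: 0.3
  kappa_ap: 0.3
- name: air
  id: 18
  category: III
  A: 40.0
  kappa_si: 0.0
  kappa_ap: 0.0
- name: rib
  id: 19
  category: IV
  A: 32.0
  kappa_si: 0.0
  kappa_ap: 0.0
- name: spine
  id: 20
  category: IV
  A: 38.0
  kappa_si: 0.0
  kappa_ap: 0.0
- name: cord
  id: 21
  category: IV
  A: 195.0
  kappa_si: 0.0
  kappa_ap: 0.0
- name: cortical_bone
  id: 22
  category: IV
  A: 28.0
  kappa_si: 0.0
  kappa_ap: 0.0
- name: cartilage
  id: 23
  category: IV
  A: 140.0
  kappa_si: 0.0
  kappa_ap: 0.0
- name: mobile_marrow
  id: 24
  category: IV
  A: 135.0
  kappa_si: 0.0
  kappa_ap: 0.0
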