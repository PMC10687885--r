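adl_scale:
  items:
  - adl_bed_mobility
  - adl_transfer
  - adl_toilet_use
  - adl_eating
  weights:
    adl_bed_mobility: 1.0
    adl_transfer: 1.0
    adl_toilet_use: 1.0
    adl_eating: 1.0
  code_range:
  - 1
  - 5
  band_cuts:
    A: 7.0
    B: 11.0
    C: 15.0
iadl_scale:
  items:
  - iadl_meal_preparation
  - iadl_housework
  - iadl_phone_use
  - iadl_managing_medications
  - iadl_managing_finances
  code_range:
  - 0
  - 3
  difficulty_cut: 1
category_triggers:
  Rehabilitation:
    type: therapy
    min_minutes_7day: 120.0
  ExtensiveServices:
    type: clinical_any
    flags:
    - iv_medication
    - tracheostomy_care
    - ventilator
  SpecialCare:
    type: clinical_any
    flags:
    - pressure_ulcer_stage3plus
    - tube_feeding
    - radiation_therapy
    - multiple_sclerosis
    - quadriplegia
  ClinicallyComplex:
    type: clinical_any
    flags:
    - pneumonia
    - dehydration
    - wound_care
    - oxygen_therapy
    - chemotherapy
    - dialysis
    - end_stage_disease
  ImpairedCognition:
    type: cognition
    min_score: 3.0
  BehaviourProblems:
    type: behaviour_any
    flags:
    - wandering
    - verbally_abusive
    - physically_abusive
    - socially_inappropriate
    - resists_care
  ReducedPhysicalFunctions:
    type: always
split_map:
  Rehabilitation:
  - adl_bands:
    - B
    - C
    - D
    group: RB
  - adl_bands: A
    iadl: some
    group: RA2
  - adl_bands: A
    iadl: none
    group: RA1
  ExtensiveServices:
  - min_services: 3.0
    group: SE3
  - min_services: 2.0
    group: SE2
  - min_services: 1.0
    group: SE1
  SpecialCare:
  - adl_bands:
    - B
    - C
    - D
    group: SSB
  - adl_bands: A
    group: SSA
  ClinicallyComplex:
  - adl_bands:
    - C
    - D
    group: CC
  - adl_bands: B
    group: CB
  - adl_bands: A
    iadl: some
    group: CA2
  - adl_bands: A
    iadl: none
    group: CA1
  ImpairedCognition:
  - adl_bands:
    - B
    - C
    - D
    group: IB
  - adl_bands: A
    iadl: some
    group: IA2
  - adl_bands: A
    iadl: none
    group: IA1
  BehaviourProblems:
  - adl_bands:
    - B
    - C
    - D
    group: BB
  - adl_bands: A
    iadl: some
    group: BA2
  - adl_bands: A
    iadl: none
    group: BA1
  ReducedPhysicalFunctions:
  - adl_bands: D
    group: PD
  - adl_bands: C
    group: PC
  - adl_bands: B
    group: PB
  - adl_bands: A
    iadl: some
    group: PA2
  - adl_bands: A
    iadl: none
    group: PA1
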