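# Default 20-variable biopsychosocial registry for ENT surgical prioritization.
# Kinds, levels, interval breakpoints (months unless noted) and per-level
# expert impact scores (1-10) encode the most natural reading of the published
# variable definitions; all are institution-overridable.
variables:
  - id: Sever
    label: Severity
    kind: ordinal
    levels: [low, moderate, high, severe]
    scores: [1, 3, 6, 9]
  - id: Urg
    label: Urgency
    kind: ordinal
    levels: [low, moderate, high, critical]
    scores: [1, 4, 7, 10]
  - id: Jclin
    label: Maximum waiting time indicated by the physician
    kind: continuous            # months; shorter allowable wait = higher impact
    breaks: [0, 3, 6, 12, 36]
    scores: [9, 7, 4, 2]
  - id: Tsuen
    label: Sleep disorder
    kind: ordinal
    levels: [none, mild, moderate, severe]
    scores: [1, 3, 6, 9]
  - id: Tlist
    label: Time on waiting list
    kind: continuous            # months accrued on the list
    breaks: [0, 6, 12, 24, 60]
    scores: [2, 4, 7, 9]
  - id: Pmcx
    label: Expected improvement due to surgery
    kind: ordinal
    levels: [low, moderate, high]
    scores: [2, 5, 9]
  - id: Dest
    label: Capacity to study (exploratory)
    kind: binary
    binary: [7, 2]
  - id: Com
    label: Chances of developing comorbidities
    kind: ordinal
    levels: [low, moderate, high]
    scores: [2, 5, 9]
  - id: Lfam
    label: Capacity of participating in family activities
    kind: ordinal
    levels: [none, partial, severe]
    scores: [2, 5, 9]
  - id: Hanor
    label: Affected area
    kind: categorical
    levels: [ear, nose, throat, head_neck]
    scores: [5, 4, 6, 8]
  - id: Opat
    label: Presence of other pathologies
    kind: binary
    binary: [8, 2]
  - id: Diag
    label: Diagnosis
    kind: categorical
    levels: [chronic_otitis, septal_deviation, chronic_sinusitis,
             tonsillar_disease, laryngeal_lesion]
    scores: [7, 4, 5, 3, 9]
  - id: Olim
    label: Other limitations
    kind: binary
    binary: [6, 2]
  - id: Ncuid
    label: Need of a caregiver
    kind: binary
    binary: [7, 2]
  - id: Rcuid
    label: Patient cares for another person
    kind: binary
    binary: [7, 2]
  - id: Dolor
    label: Pain scale
    kind: ordinal
    levels: [none, mild, moderate, severe]
    scores: [1, 3, 6, 9]
  - id: Dtrab
    label: Capacity to work
    kind: ordinal
    levels: [none, partial, total]
    scores: [2, 5, 9]
  - id: Acc
    label: Type of residence area (exploratory)
    kind: binary
    binary: [6, 3]
  - id: Dtras
    label: Difficulty in transferring
    kind: ordinal
    levels: [none, some, severe]
    scores: [2, 5, 8]
  - id: Ccrit
    label: Need for clinical bed
    kind: binary
    binary: [8, 1]
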