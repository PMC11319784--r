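# Progress-note section schema: a synthetic 15-type SOAP-style
# reconstruction (the original progress-note type list is not
# redistributable).  Intended for simulation and as an editable template.
types:
  - name: Chief complaint
    definition: the main problem the patient reports today
    example_headings: ["chief complaint", "CC"]
  - name: Interval history
    definition: events and symptom changes since the previous note
    example_headings: ["interval history", "INTERVAL EVENTS"]
  - name: Overnight events
    definition: notable events that occurred overnight
    example_headings: ["overnight events", "OVERNIGHT COURSE"]
  - name: Subjective
    definition: the patient's own report of symptoms and concerns
    example_headings: ["subjective", "SUBJECTIVE"]
  - name: Vital signs
    definition: temperature, blood pressure, heart rate and other vitals
    example_headings: ["vital signs", "VITALS"]
  - name: Physical examination
    definition: findings of today's physical exam
    example_headings: ["physical examination", "EXAM"]
  - name: Lab results
    definition: recent laboratory test results
    example_headings: ["labs", "LAB RESULTS"]
  - name: Imaging
    definition: results of imaging studies such as x-ray, CT, or MRI
    example_headings: ["imaging", "RADIOLOGY"]
  - name: Medications
    definition: the patient's current medication list
    example_headings: ["medications", "CURRENT MEDICATIONS"]
  - name: Allergies
    definition: substances the patient is allergic to and the reactions
    example_headings: ["allergies", "ALLERGIES"]
  - name: Assessment
    definition: the clinician's assessment of the patient's problems
    example_headings: ["assessment", "IMPRESSION"]
  - name: Plan
    definition: the plan of care for each active problem
    example_headings: ["plan", "PLAN"]
  - name: Assessment and plan
    definition: combined assessment and plan discussion by problem
    example_headings: ["assessment and plan", "A/P"]
  - name: Code status
    definition: the patient's resuscitation preferences
    example_headings: ["code status", "CODE"]
  - name: Unknown
    definition: content that does not fit any of the defined section types
    example_headings: ["addendum", "MISCELLANEOUS"]
label_map:
  Subsection: Unknown
  PE: Physical examination
  A&P: Assessment and plan
  Laboratory: Lab results
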