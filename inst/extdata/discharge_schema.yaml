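# Discharge-summary section schema: 27 canonical types plus a raw-label map
# collapsing redundant annotation categories.  Definitions and example
# headings are authored, editable reconstructions intended for prompting and
# simulation; adapt them to your own corpus by copying this file.
types:
  - name: Admit date
    definition: the date of the patient's admit
    example_headings: ["admission date", "date of admission"]
  - name: Discharge date
    definition: the date the patient was discharged from the hospital
    example_headings: ["discharge date", "date of discharge"]
  - name: Patient service
    definition: the hospital service or unit that cared for the patient
    example_headings: ["service", "SERVICE"]
  - name: Reason for admission
    definition: the problem or event that brought the patient to the hospital
    example_headings: ["reason for admission", "CHIEF COMPLAINT"]
  - name: Admission diagnosis
    definition: the diagnosis assigned at the time of admission
    example_headings: ["admission diagnosis", "ADMITTING DIAGNOSIS"]
  - name: Discharge diagnosis
    definition: the principal diagnosis at the time of discharge
    example_headings: ["discharge diagnosis", "FINAL DIAGNOSIS"]
  - name: Other diagnosis
    definition: secondary or comorbid diagnoses beyond the principal one
    example_headings: ["other diagnoses", "SECONDARY DIAGNOSES"]
  - name: History of present illness
    definition: the narrative of the current illness leading to this admission
    example_headings: ["history of present illness", "HPI"]
  - name: Past medical history
    definition: the patient's prior medical conditions and chronic illnesses
    example_headings: ["past medical history", "PMH"]
  - name: Past surgical history
    definition: operations and surgical procedures the patient had before
    example_headings: ["past surgical history", "PSH"]
  - name: Gynecologic history
    definition: obstetric and gynecologic history of the patient
    example_headings: ["gynecologic history", "OB/GYN HISTORY"]
  - name: Social history
    definition: lifestyle, occupation, living situation, tobacco and alcohol use
    example_headings: ["social history", "SOCIAL HISTORY"]
  - name: Family history
    definition: illnesses among the patient's blood relatives
    example_headings: ["family history", "FAMILY HISTORY"]
  - name: Allergies
    definition: substances the patient is allergic to and the reactions
    example_headings: ["allergies", "ALLERGIES"]
  - name: Admission medications
    definition: medications the patient was taking at admission
    example_headings: ["medications on admission", "ADMISSION MEDICATIONS"]
  - name: Discharge medications
    definition: medications prescribed for the patient at discharge
    example_headings: ["discharge medications", "MEDICATIONS ON DISCHARGE"]
  - name: Physical examination
    definition: findings of the physical exam performed on the patient
    example_headings: ["physical examination", "PHYSICAL EXAM"]
  - name: Lab studies
    definition: laboratory test results such as blood work and cultures
    example_headings: ["laboratory data", "LABS"]
  - name: Patient procedures
    definition: procedures and operations performed during this stay
    example_headings: ["procedures", "OPERATIONS AND PROCEDURES"]
  - name: Hospital course
    definition: the narrative of events and treatment during the hospital stay
    example_headings: ["hospital course", "BRIEF HOSPITAL COURSE"]
  - name: Discharge condition
    definition: the patient's clinical condition at the time of discharge
    example_headings: ["condition on discharge", "DISCHARGE CONDITION"]
  - name: Discharge instructions
    definition: instructions given to the patient for care after discharge
    example_headings: ["discharge instructions", "INSTRUCTIONS"]
  - name: Follow-up
    definition: planned follow-up appointments and monitoring after discharge
    example_headings: ["follow-up", "FOLLOW UP PLANS"]
  - name: Attending physician
    definition: the attending physician responsible for the patient's care
    example_headings: ["attending", "ATTENDING PHYSICIAN"]
  - name: Admitting physician
    definition: the physician who admitted the patient
    example_headings: ["admitting physician", "ADMITTED BY"]
  - name: Patient comments
    definition: remarks attributed to the patient or about patient preferences
    example_headings: ["patient comments", "COMMENTS"]
  - name: Unknown
    definition: content that does not fit any of the defined section types
    example_headings: ["addendum", "MISCELLANEOUS"]
label_map:
  Subsection: Unknown
  Physical: Physical examination
  Laboratory data: Lab studies
  Followup: Follow-up
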