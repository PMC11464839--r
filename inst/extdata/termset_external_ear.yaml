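# Preferred-term case definition: congenital anomalies of the external ear.
# MedDRA PT names are authoritative; codes are recorded where reliable and
# left null where the published transcription is missing or ambiguous
# (congenital aural fistula has no usable code; macrotia's published code
# collides with low set ears).
name: external_ear_congenital_anomalies
terms:
  - pt_name: accessory auricle
    pt_code: 10000361
  - pt_name: anomaly of external ear congenital
    pt_code: 10062339
  - pt_name: anotia
    pt_code: 10002654
  - pt_name: congenital aural fistula
    pt_code: null
  - pt_name: constricted ear deformity
    pt_code: 10071233
  - pt_name: external auditory canal atresia
    pt_code: 10054875
  - pt_name: low set ears
    pt_code: 10024929
  - pt_name: macrotia
    pt_code: null
  - pt_name: microtia
    pt_code: 10027555
  - pt_name: protuberant ear
    pt_code: 10071232
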