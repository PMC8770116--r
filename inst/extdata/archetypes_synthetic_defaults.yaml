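- name: pacifier
  material_default: silicone
  d_p_cm: 0.25
  v_p_cm3: 10.0
  v_f_cm3: 10.0
  a_contact_cm2: 10.0
- name: doll
  material_default: PVC
  d_p_cm: 0.2
  v_p_cm3: 50.0
  v_f_cm3: 10.0
  a_contact_cm2: 10.0
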