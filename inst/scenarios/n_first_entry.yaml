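# Successful N-terminus-first entry through the open bottom mouth.
# The gate opens, the peptide climbs the cavity axis N-terminus first while
# a ladder of salt bridges forms and breaks, and the gate closes after entry.
name: n_first_entry
peptide: OmpC_N
orientation: n_lead
n_frames: 200
motion:
  kind: axial
  z_start: -10.0
  move_start: 15
  speed: 0.8
  move_end: 95
gate_open:
  - [10, 150]
bridges:
  - {pep_resno: 2,  skp_chain: B, skp_resno: 71, form: 20,  break: 40}
  - {pep_resno: 2,  skp_chain: C, skp_resno: 71, form: 42,  break: 70}
  - {pep_resno: 7,  skp_chain: C, skp_resno: 55, form: 60,  break: 85}
  - {pep_resno: 12, skp_chain: C, skp_resno: 71, form: 90,  break: 110}
  - {pep_resno: 18, skp_chain: B, skp_resno: 55, form: 100, break: 125}
  - {pep_resno: 2,  skp_chain: A, skp_resno: 91, form: 115, break: 140}
truth:
  verdict: entered
  terminus_first: N_first
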