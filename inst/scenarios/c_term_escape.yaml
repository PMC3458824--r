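# Charge-poor C-terminal fragment led by its C-terminus: a single transient
# bridge forms at the bottom, then the peptide retreats and escapes.
name: c_term_escape
peptide: OmpC_C
orientation: c_lead
n_frames: 150
motion:
  kind: axial
  z_start: -2.0
  move_start: 45
  speed: -0.35
  move_end: 150
gate_open: []
bridges:
  - {pep_resno: 10, skp_chain: C, skp_resno: 49, form: 15, break: 40}
truth:
  verdict: escaped
  terminus_first: none
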