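# Gate never opens; the peptide approaches the closed mouth from below and
# ends adhered to the bottom of the chaperone by persistent salt bridges.
name: closed_gate_adhesion
peptide: OmpC_N
orientation: n_lead
n_frames: 200
motion:
  kind: axial
  z_start: -20.0
  move_start: 0
  speed: 0.3
  move_end: 60
gate_open: []
bridges:
  - {pep_resno: 2, skp_chain: B, skp_resno: 55, form: 70,  break: 120}
  - {pep_resno: 7, skp_chain: C, skp_resno: 49, form: 90,  break: .na}
  - {pep_resno: 2, skp_chain: A, skp_resno: 49, form: 130, break: .na}
truth:
  verdict: adhered_outside
  terminus_first: none
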