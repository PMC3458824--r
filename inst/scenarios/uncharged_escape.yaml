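# Charge-neutralized (all-Ala) peptide: no charge sites exist, no bridges
# can form, and the peptide drifts out of the cavity region.
name: uncharged_escape
peptide: OmpC_N_Amut
orientation: n_lead
n_frames: 150
motion:
  kind: axial
  z_start: -5.0
  move_start: 0
  speed: -0.4
  move_end: 150
gate_open: []
bridges: []
truth:
  verdict: escaped
  terminus_first: none
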