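# Peptide placed sideways next to the outer wall, below the mouth level;
# it drifts radially away without ever forming a bridge.
name: side_approach
peptide: OmpC_N
orientation: n_lead
n_frames: 150
motion:
  kind: side
  r_start: 30.0
  speed: 0.3
  z_level: -5.0
gate_open: []
bridges: []
truth:
  verdict: escaped
  terminus_first: none
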