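tool: nucleopack
version: 0.1.0
command: pmot
flags:
  trajectory: x.csv
seed: 1
time: 2026-10-01T19:35:46+0000
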