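blocks:
  - name: strain
    type: categorical
    levels: [wild-type, PET, EGFP, iL3EGFP, iL3PET]
    codes: [0, 1]
  - name: inducer
    type: categorical
    levels: [control, IPTG, IPTG+PPDA, PPDA]
    codes: [0, 1]
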