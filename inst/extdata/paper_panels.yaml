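# Built-in configuration: all ten figure-panel scenario sets.
seed: 20231016
panels:
  - fig1a
  - fig1b
  - fig2b
  - fig3b
  - fig3c
  - fig4
  - fig5a
  - fig5b
  - supp_xpa
  - supp_sprtn
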