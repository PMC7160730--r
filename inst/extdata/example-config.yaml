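# Example configuration: control circulation at rest with one predefined
# reduced-conduction scenario. Any omitted key keeps its default value.
heart_rate: 72
duration: 60
scenarios:
  tcv50:
    t_Vmax: 0.3885
    K_Vc: 0.982
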