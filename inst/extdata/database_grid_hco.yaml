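# The eight-parameter screening grid of the coupled-pair model: leak
# reversal potential at five values, seven maximal conductances at
# eight fractions of their canonical values; rows with both synaptic
# conductances absent are excluded.
values:
  E_leak: [-70, -65, -60, -55, -50]
  g_leak: [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75]
  g_SynS: [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75]
  g_SynG: [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75]
  g_P:    [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75]
  g_CaS:  [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75]
  g_h:    [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75]
  g_K2:   [0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75]
exclude_all_zero: [g_SynS, g_SynG]
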