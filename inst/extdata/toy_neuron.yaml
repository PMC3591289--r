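# Small complete two-current demonstration model (synthetic values).
name: toy_neuron
capacitance: 0.5        # nF
injected_current: 0     # nA
currents:
  - name: leak
    reversal_potential: -60    # mV; overridden per case
    max_conductance: 8         # nS; overridden per case
  - name: P
    reversal_potential: 45
    max_conductance: 7
    activation:
      name: m_P
      exponent: 1
      v_half: -39
      slope: -5
      tau: {kind: constant, value: 0.01}
  - name: K2
    reversal_potential: -70
    max_conductance: 80
    activation:
      name: m_K2
      exponent: 2
      v_half: -10
      slope: -8
      tau: {kind: bell, base: 0.05, amp: 0.2, v_peak: -20, width: 20}
    inactivation:
      name: h_K2
      exponent: 1
      v_half: -30
      slope: 6
      tau: {kind: sigmoid, base: 0.1, amp: 0.5, v_half: -40, slope: 10}
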