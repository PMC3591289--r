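# Template for the leech heart interneuron (HN) model: the canonical
# eight-current single-compartment structure, with SYNTHETIC placeholder
# kinetics.  The published kinetics of these currents are not included
# here; to reproduce database-specific numbers, transcribe the
# half-activation voltages, slopes, time constants, canonical maximal
# conductances and reversal potentials from the published model
# definition of Hill et al. and replace every value marked below.  All
# placeholder values are generic sigmoids chosen only so that this file
# parses and validates; they are NOT the published kinetics.
name: leech_hn_synthetic_template
capacitance: 0.5          # nF -- placeholder
injected_current: 0
currents:
  - name: leak
    reversal_potential: -60       # overridden per case (E_leak grid)
    max_conductance: 8            # overridden per case (g_leak grid)
  - name: Na            # fast sodium
    reversal_potential: 45
    max_conductance: 200          # placeholder canonical value
    activation: {name: m_Na, exponent: 3, v_half: -29, slope: -6,
                 tau: {kind: constant, value: 0.0001}}
    inactivation: {name: h_Na, exponent: 1, v_half: -30, slope: 6,
                   tau: {kind: bell, base: 0.004, amp: 0.01, v_peak: -30,
                         width: 15}}
  - name: P             # persistent sodium
    reversal_potential: 45
    max_conductance: 7
    activation: {name: m_P, exponent: 1, v_half: -39, slope: -5,
                 tau: {kind: constant, value: 0.01}}
  - name: CaF           # fast low-threshold calcium
    reversal_potential: 135
    max_conductance: 5
    activation: {name: m_CaF, exponent: 2, v_half: -47, slope: -5,
                 tau: {kind: constant, value: 0.01}}
    inactivation: {name: h_CaF, exponent: 1, v_half: -55, slope: 4,
                   tau: {kind: bell, base: 0.06, amp: 0.3, v_peak: -50,
                         width: 20}}
  - name: CaS           # slow low-threshold calcium
    reversal_potential: 135
    max_conductance: 3.2
    activation: {name: m_CaS, exponent: 2, v_half: -47, slope: -6,
                 tau: {kind: constant, value: 0.02}}
    inactivation: {name: h_CaS, exponent: 1, v_half: -55, slope: 6,
                   tau: {kind: bell, base: 0.2, amp: 2, v_peak: -50,
                         width: 25}}
  - name: h             # hyperpolarization-activated cation
    reversal_potential: -21
    max_conductance: 4
    activation: {name: m_h, exponent: 2, v_half: -70, slope: 6,
                 tau: {kind: sigmoid, base: 0.7, amp: 1.5, v_half: -75,
                       slope: 10}}
  - name: K1            # delayed-rectifier-like potassium
    reversal_potential: -70
    max_conductance: 100
    activation: {name: m_K1, exponent: 2, v_half: -21, slope: -8,
                 tau: {kind: constant, value: 0.002}}
    inactivation: {name: h_K1, exponent: 1, v_half: -28, slope: 10,
                   tau: {kind: constant, value: 0.2}}
  - name: K2            # persistent potassium
    reversal_potential: -70
    max_conductance: 80
    activation: {name: m_K2, exponent: 2, v_half: -18, slope: -8,
                 tau: {kind: constant, value: 0.05}}
  - name: KA            # fast transient potassium
    reversal_potential: -70
    max_conductance: 80
    activation: {name: m_KA, exponent: 2, v_half: -44, slope: -8,
                 tau: {kind: constant, value: 0.005}}
    inactivation: {name: h_KA, exponent: 1, v_half: -63, slope: 6,
                   tau: {kind: constant, value: 0.05}}
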