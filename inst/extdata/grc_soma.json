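{
  "comment": [
    "Granule-cell soma model: single compartment, gating-particle channels.",
    "Kinetic forms and coefficients adapted from the granule-cell model",
    "lineage of D'Angelo et al. (2001, J Neurosci 21:759) and subsequent",
    "reimplementations; densities calibrated so the cell is silent at rest",
    "(~-73 mV) and integrates repeated mossy-fiber EPSPs before spiking.",
    "Units: S/cm2 for densities, mV, ms, mM; rates in 1/ms."
  ],
  "class": "GRC",
  "area_um2": 299.0,
  "cm_uF_cm2": 1.0,
  "celsius": 30.0,
  "v_init": -73.0,
  "spike_threshold_mV": -20.0,
  "min_isi_ms": 1.0,
  "e_na": 87.39,
  "e_k": -84.69,
  "calcium": { "depth_um": 0.2, "beta_ms": 1.5, "ca0_mM": 1e-04, "cao_mM": 2.0 },
  "channels": [
    {
      "name": "na_f", "gbar_S_cm2": 0.013, "erev": 87.39,
      "q10": 3.0, "temp0": 20.0,
      "gates": [
        { "power": 3, "kind": "alpha_beta",
          "alpha": { "form": "linoid", "A": -0.3, "V0": -19.0, "K": -10.0 },
          "beta":  { "form": "exponential", "A": 12.0, "V0": -44.0, "K": -18.182 } },
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "exponential", "A": 0.105, "V0": -44.0, "K": -3.333 },
          "beta":  { "form": "sigmoid", "A": 1.5, "V0": -11.0, "K": -5.0 } }
      ]
    },
    {
      "name": "na_r", "gbar_S_cm2": 0.0005, "erev": 87.39,
      "q10": 3.0, "temp0": 20.0,
      "gates": [
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "sigmoid", "A": 1.1, "V0": -20.0, "K": -10.0 },
          "beta":  { "form": "sigmoid", "A": 1.1, "V0": -50.0, "K": 10.0 } },
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "exponential", "A": 0.08, "V0": -60.0, "K": -25.0 },
          "beta":  { "form": "exponential", "A": 0.08, "V0": -60.0, "K": 25.0 } }
      ]
    },
    {
      "name": "na_p", "gbar_S_cm2": 2e-05, "erev": 87.39,
      "q10": 3.0, "temp0": 30.0,
      "gates": [
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "linoid", "A": -0.91, "V0": -42.0, "K": -5.0 },
          "beta":  { "form": "linoid", "A": 0.62, "V0": -42.0, "K": 5.0 } }
      ]
    },
    {
      "name": "k_v", "gbar_S_cm2": 0.003, "erev": -84.69,
      "q10": 3.0, "temp0": 6.3,
      "gates": [
        { "power": 4, "kind": "alpha_beta",
          "alpha": { "form": "linoid", "A": -0.01, "V0": -25.0, "K": -10.0 },
          "beta":  { "form": "exponential", "A": 0.125, "V0": -35.0, "K": -80.0 } }
      ]
    },
    {
      "name": "k_a", "gbar_S_cm2": 0.0032, "erev": -84.69,
      "q10": 3.0, "temp0": 20.0,
      "gates": [
        { "power": 3, "kind": "alpha_beta",
          "alpha": { "form": "sigmoid", "A": 4.88826, "V0": -9.17203, "K": -23.32708 },
          "beta":  { "form": "exponential", "A": 0.99285, "V0": -18.27914, "K": -19.47175 } },
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "sigmoid", "A": 0.11042, "V0": -111.33209, "K": 12.8433 },
          "beta":  { "form": "sigmoid", "A": 0.10353, "V0": -49.9537, "K": -8.90123 } }
      ]
    },
    {
      "name": "k_ir", "gbar_S_cm2": 0.0009, "erev": -84.69,
      "q10": 3.0, "temp0": 20.0,
      "gates": [
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "exponential", "A": 0.13289, "V0": -83.94, "K": -24.3902 },
          "beta":  { "form": "exponential", "A": 0.16994, "V0": -83.94, "K": 35.714 } }
      ]
    },
    {
      "name": "k_ca", "gbar_S_cm2": 0.004, "erev": -84.69,
      "q10": 3.0, "temp0": 30.0,
      "gates": [
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "ca_on", "A": 2.5, "B": 0.0015, "K": -11.765 },
          "beta":  { "form": "ca_off", "A": 1.5, "B": 0.00015, "K": -11.765 } }
      ]
    },
    {
      "name": "k_slow", "gbar_S_cm2": 0.00035, "erev": -84.69,
      "q10": 3.0, "temp0": 22.0,
      "gates": [
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "exponential", "A": 0.0033, "V0": -30.0, "K": 40.0 },
          "beta":  { "form": "exponential", "A": 0.0033, "V0": -30.0, "K": -20.0 } }
      ]
    },
    {
      "name": "ca_hva", "gbar_S_cm2": 0.00046, "erev": "ca",
      "q10": 3.0, "temp0": 20.0,
      "gates": [
        { "power": 2, "kind": "alpha_beta",
          "alpha": { "form": "exponential", "A": 0.04944, "V0": -29.06, "K": 15.87 },
          "beta":  { "form": "exponential", "A": 0.08298, "V0": -18.66, "K": -25.641 } },
        { "power": 1, "kind": "alpha_beta",
          "alpha": { "form": "exponential", "A": 0.0013, "V0": -48.0, "K": -18.183 },
          "beta":  { "form": "exponential", "A": 0.0013, "V0": -48.0, "K": 83.33 } }
      ]
    },
    { "name": "leak", "gbar_S_cm2": 5.68e-05, "erev": -58.0,
      "q10": 1.0, "temp0": 30.0, "gates": [] },
    { "name": "leak_gaba", "gbar_S_cm2": 3e-05, "erev": -65.0,
      "q10": 1.0, "temp0": 30.0, "gates": [] }
  ]
}
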