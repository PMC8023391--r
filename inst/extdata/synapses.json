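{
  "comment": [
    "Synapse models. Presynaptic terminal: three-state (recovered/active/",
    "inactive) release scheme in the Tsodyks-Markram form used by the",
    "granular-layer synapse models of Nieus et al. (2006, J Neurophysiol",
    "95:686); transmitter is emitted as a rectangular pulse while a release",
    "event is active. Receptors: kinetic first-order schemes - AMPA 3",
    "states, NMDA 5 states, GABA-A 8 states in alpha1 and alpha6 variants",
    "(Nieus et al. 2014 lineage). Peak conductances are fixed at 1200 pS",
    "(AMPA), 18800 pS (NMDA), 918/132 pS (GABA alpha1/alpha6). Transition",
    "rates: rate = base + t_mult * T with T the transmitter concentration",
    "(mM); rate constants adapted/calibrated to published EPSC and IPSC",
    "time courses. Units: pS, mV, ms, mM."
  ],
  "presyn": {
    "u": 0.43,
    "tau_rec_ms": 35.0,
    "tau_in_ms": 3.0,
    "t_max_mM": 1.0,
    "t_dur_ms": 0.3
  },
  "mg_block": {
    "mg_mM": 1.0,
    "slope_per_mV": 0.062,
    "k_mM": 3.57
  },
  "receptors": {
    "ampa": {
      "gmax_pS": 1200.0,
      "vrev_mV": 0.0,
      "states": [
        "C",
        "O",
        "D"
      ],
      "open": [
        "O"
      ],
      "transitions": [
        {
          "from": "C",
          "to": "O",
          "base": 0.0,
          "t_mult": 0.5
        },
        {
          "from": "O",
          "to": "C",
          "base": 0.9,
          "t_mult": 0.0
        },
        {
          "from": "O",
          "to": "D",
          "base": 0.5,
          "t_mult": 0.0
        },
        {
          "from": "D",
          "to": "C",
          "base": 0.02,
          "t_mult": 0.0
        }
      ]
    },
    "nmda": {
      "gmax_pS": 18800.0,
      "vrev_mV": 0.0,
      "mg_block": true,
      "states": [
        "C1",
        "C2",
        "C3",
        "O",
        "D"
      ],
      "open": [
        "O"
      ],
      "transitions": [
        {
          "from": "C1",
          "to": "C2",
          "base": 0.0,
          "t_mult": 1.0
        },
        {
          "from": "C2",
          "to": "C1",
          "base": 0.06,
          "t_mult": 0.0
        },
        {
          "from": "C2",
          "to": "C3",
          "base": 0.0,
          "t_mult": 1.0
        },
        {
          "from": "C3",
          "to": "C2",
          "base": 0.06,
          "t_mult": 0.0
        },
        {
          "from": "C3",
          "to": "O",
          "base": 0.05,
          "t_mult": 0.0
        },
        {
          "from": "O",
          "to": "C3",
          "base": 0.06,
          "t_mult": 0.0
        },
        {
          "from": "C3",
          "to": "D",
          "base": 0.004,
          "t_mult": 0.0
        },
        {
          "from": "D",
          "to": "C3",
          "base": 0.001,
          "t_mult": 0.0
        }
      ]
    },
    "gaba_a1": {
      "gmax_pS": 918.0,
      "vrev_mV": -65.0,
      "states": [
        "C",
        "CA1",
        "CA2",
        "OA1",
        "OA2",
        "DA1",
        "DA2",
        "DA2f"
      ],
      "open": [
        "OA1",
        "OA2"
      ],
      "transitions": [
        {
          "from": "C",
          "to": "CA1",
          "base": 0.0,
          "t_mult": 20.0
        },
        {
          "from": "CA1",
          "to": "C",
          "base": 0.15,
          "t_mult": 0.0
        },
        {
          "from": "CA1",
          "to": "CA2",
          "base": 0.0,
          "t_mult": 10.0
        },
        {
          "from": "CA2",
          "to": "CA1",
          "base": 0.3,
          "t_mult": 0.0
        },
        {
          "from": "CA1",
          "to": "OA1",
          "base": 0.06,
          "t_mult": 0.0
        },
        {
          "from": "OA1",
          "to": "CA1",
          "base": 0.25,
          "t_mult": 0.0
        },
        {
          "from": "CA2",
          "to": "OA2",
          "base": 1.2,
          "t_mult": 0.0
        },
        {
          "from": "OA2",
          "to": "CA2",
          "base": 0.1,
          "t_mult": 0.0
        },
        {
          "from": "CA1",
          "to": "DA1",
          "base": 0.005,
          "t_mult": 0.0
        },
        {
          "from": "DA1",
          "to": "CA1",
          "base": 0.002,
          "t_mult": 0.0
        },
        {
          "from": "CA2",
          "to": "DA2",
          "base": 0.02,
          "t_mult": 0.0
        },
        {
          "from": "DA2",
          "to": "CA2",
          "base": 0.005,
          "t_mult": 0.0
        },
        {
          "from": "DA2",
          "to": "DA2f",
          "base": 0.003,
          "t_mult": 0.0
        },
        {
          "from": "DA2f",
          "to": "DA2",
          "base": 0.0005,
          "t_mult": 0.0
        }
      ]
    },
    "gaba_a6": {
      "gmax_pS": 132.0,
      "vrev_mV": -65.0,
      "states": [
        "C",
        "CA1",
        "CA2",
        "OA1",
        "OA2",
        "DA1",
        "DA2",
        "DA2f"
      ],
      "open": [
        "OA1",
        "OA2"
      ],
      "transitions": [
        {
          "from": "C",
          "to": "CA1",
          "base": 0.0,
          "t_mult": 20.0
        },
        {
          "from": "CA1",
          "to": "C",
          "base": 0.08,
          "t_mult": 0.0
        },
        {
          "from": "CA1",
          "to": "CA2",
          "base": 0.0,
          "t_mult": 10.0
        },
        {
          "from": "CA2",
          "to": "CA1",
          "base": 0.15,
          "t_mult": 0.0
        },
        {
          "from": "CA1",
          "to": "OA1",
          "base": 0.04,
          "t_mult": 0.0
        },
        {
          "from": "OA1",
          "to": "CA1",
          "base": 0.12,
          "t_mult": 0.0
        },
        {
          "from": "CA2",
          "to": "OA2",
          "base": 0.8,
          "t_mult": 0.0
        },
        {
          "from": "OA2",
          "to": "CA2",
          "base": 0.03,
          "t_mult": 0.0
        },
        {
          "from": "CA1",
          "to": "DA1",
          "base": 0.005,
          "t_mult": 0.0
        },
        {
          "from": "DA1",
          "to": "CA1",
          "base": 0.002,
          "t_mult": 0.0
        },
        {
          "from": "CA2",
          "to": "DA2",
          "base": 0.015,
          "t_mult": 0.0
        },
        {
          "from": "DA2",
          "to": "CA2",
          "base": 0.004,
          "t_mult": 0.0
        },
        {
          "from": "DA2",
          "to": "DA2f",
          "base": 0.002,
          "t_mult": 0.0
        },
        {
          "from": "DA2f",
          "to": "DA2",
          "base": 0.0004,
          "t_mult": 0.0
        }
      ]
    }
  }
}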