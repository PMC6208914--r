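{
  "izhikevich": {
    "common": {
      "v_th": 30
    },
    "variants": [
      {
        "label": "A",
        "name": "Tonic spiking",
        "a": 0.02,
        "b": 0.2,
        "c": -65,
        "d": 6,
        "xi": 15.1,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "B",
        "name": "Phasic spiking",
        "a": 0.02,
        "b": 0.25,
        "c": -65,
        "d": 6,
        "xi": 4.3,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "C",
        "name": "Tonic bursting",
        "a": 0.02,
        "b": 0.2,
        "c": -50,
        "d": 2,
        "xi": 15.1,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "D",
        "name": "Phasic bursting",
        "a": 0.02,
        "b": 0.25,
        "c": -55,
        "d": 0.05,
        "xi": 4.3,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "E",
        "name": "Mixed mode",
        "a": 0.02,
        "b": 0.2,
        "c": -55,
        "d": 4,
        "xi": 15.1,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "F",
        "name": "Spike frequency adaptation",
        "a": 0.01,
        "b": 0.2,
        "c": -65,
        "d": 8,
        "xi": 15.1,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "G",
        "name": "Class 1 excitable",
        "a": 0.02,
        "b": -0.1,
        "c": -55,
        "d": 6,
        "xi": 49,
        "i_ext": 0,
        "included": false
      },
      {
        "label": "H",
        "name": "Class 2 excitable",
        "a": 0.2,
        "b": 0.26,
        "c": -65,
        "d": 0,
        "xi": 5.6,
        "i_ext": -0.5,
        "included": true
      },
      {
        "label": "I",
        "name": "Spike latency",
        "a": 0.02,
        "b": 0.2,
        "c": -65,
        "d": 6,
        "xi": 15.1,
        "i_ext": 0,
        "included": false
      },
      {
        "label": "J",
        "name": "Subthreshold oscillation",
        "a": 0.05,
        "b": 0.26,
        "c": -60,
        "d": 0,
        "xi": 1.8,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "K",
        "name": "Resonator",
        "a": 0.1,
        "b": 0.26,
        "c": -60,
        "d": -1,
        "xi": 2.4,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "L",
        "name": "Integrator",
        "a": 0.02,
        "b": -0.1,
        "c": -55,
        "d": 6,
        "xi": 49,
        "i_ext": 0,
        "included": false
      },
      {
        "label": "M",
        "name": "Rebound spike",
        "a": 0.03,
        "b": 0.25,
        "c": -60,
        "d": 4,
        "xi": 4.5,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "N",
        "name": "Rebound burst",
        "a": 0.03,
        "b": 0.25,
        "c": -52,
        "d": 0,
        "xi": 4.5,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "O",
        "name": "Threshold variability",
        "a": 0.03,
        "b": 0.25,
        "c": -60,
        "d": 4,
        "xi": 4.5,
        "i_ext": 0,
        "included": false
      },
      {
        "label": "P",
        "name": "Bistability",
        "a": 0.1,
        "b": 0.26,
        "c": -60,
        "d": 0,
        "xi": 0.87,
        "i_ext": 0.24,
        "included": true
      },
      {
        "label": "Q",
        "name": "Depolarizing after-potential",
        "a": 1,
        "b": 0.2,
        "c": -60,
        "d": -21,
        "xi": 17.8,
        "i_ext": 0,
        "included": true
      },
      {
        "label": "R",
        "name": "Accommodation",
        "a": 0.02,
        "b": 1,
        "c": -55,
        "d": 4,
        "xi": 1,
        "i_ext": 0,
        "included": false
      },
      {
        "label": "S",
        "name": "Inhibition-induced spiking",
        "a": -0.02,
        "b": -1,
        "c": -60,
        "d": 8,
        "xi": 4.5,
        "i_ext": 80,
        "included": true
      },
      {
        "label": "T",
        "name": "Inhibition-induced bursting",
        "a": -0.026,
        "b": -1,
        "c": -45,
        "d": -2,
        "xi": 4.8,
        "i_ext": 80,
        "included": false
      }
    ]
  },
  "amat": {
    "common": {
      "e_l": -70,
      "omega": -65,
      "c_m": 200,
      "tau_m": 10,
      "tau_1": 10,
      "tau_2": 200,
      "tau_v": 5,
      "tau_ref": 2,
      "tau_syn_e": 1,
      "tau_syn_i": 3
    },
    "variants": [
      {
        "label": "A",
        "name": "Tonic spiking",
        "alpha1": 10,
        "alpha2": 0,
        "beta": 0,
        "included": true
      },
      {
        "label": "B",
        "name": "Phasic spiking",
        "alpha1": 10,
        "alpha2": 0,
        "beta": -0.3,
        "included": true
      },
      {
        "label": "C",
        "name": "Tonic bursting",
        "alpha1": -0.5,
        "alpha2": 0.35,
        "beta": 0,
        "included": true
      },
      {
        "label": "D",
        "name": "Phasic bursting",
        "alpha1": -0.5,
        "alpha2": 0.35,
        "beta": -0.3,
        "included": true
      },
      {
        "label": "E",
        "name": "Mixed mode",
        "alpha1": -0.8,
        "alpha2": 0.7,
        "beta": 0,
        "included": true
      },
      {
        "label": "F",
        "name": "Spike frequency adaptation",
        "alpha1": 10,
        "alpha2": 1,
        "beta": 0,
        "included": true
      },
      {
        "label": "G",
        "name": "Class 1 excitable",
        "alpha1": 15,
        "alpha2": 3,
        "beta": 0,
        "included": true
      },
      {
        "label": "H",
        "name": "Class 2 excitable",
        "alpha1": 15,
        "alpha2": -0.05,
        "beta": 0,
        "included": true
      },
      {
        "label": "I",
        "name": "Spike latency",
        "alpha1": 10,
        "alpha2": 0,
        "beta": -1,
        "included": true
      },
      {
        "label": "J",
        "name": "Subthreshold oscillations",
        "alpha1": 1,
        "alpha2": 0,
        "beta": 0.2,
        "included": true
      },
      {
        "label": "K",
        "name": "Resonator",
        "alpha1": 10,
        "alpha2": 0,
        "beta": 0.5,
        "included": true
      },
      {
        "label": "L",
        "name": "Integrator",
        "alpha1": 10,
        "alpha2": 0,
        "beta": 0,
        "included": false
      },
      {
        "label": "M",
        "name": "Rebound spiking",
        "alpha1": 10,
        "alpha2": 0,
        "beta": -2.5,
        "included": true
      },
      {
        "label": "N",
        "name": "Rebound bursting",
        "alpha1": -0.5,
        "alpha2": 0.35,
        "beta": -2.5,
        "included": true
      },
      {
        "label": "O",
        "name": "Threshold variability",
        "alpha1": 10,
        "alpha2": 0,
        "beta": -0.5,
        "included": true
      },
      {
        "label": "P",
        "name": "Bistability",
        "alpha1": 20,
        "alpha2": -0.4,
        "beta": 0,
        "included": true
      },
      {
        "label": "Q",
        "name": "Depolarizing after-potential",
        "alpha1": 25,
        "alpha2": -1,
        "beta": 0,
        "included": true
      },
      {
        "label": "R",
        "name": "Accommodation",
        "alpha1": 10,
        "alpha2": 0,
        "beta": -0.5,
        "included": false
      },
      {
        "label": "S",
        "name": "Inhibition-induced spiking",
        "alpha1": 20,
        "alpha2": 0,
        "beta": 2,
        "included": true
      },
      {
        "label": "T",
        "name": "Inhibition-induced bursting",
        "alpha1": -0.5,
        "alpha2": 0.35,
        "beta": 2,
        "included": true
      }
    ]
  }
}
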