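{
  "name": "mGluR1 linear bind-activate chain (placeholder rates)",
  "comment": "Three-state chain R -> RG -> A: glutamate binding to the resting receptor followed by a conformational activation step, the topology of a perisynaptic metabotropic receptor read out by conformational FRET. GPCR-like kinetics: binding an order of magnitude slower than at ionotropic receptors (kon 1e6 /M/s, Kd 100 uM) and a slow activation step, so a brief synaptic transient activates the receptor sub-maximally and the late (tail) glutamate controls the response. Placeholder rates referenced to room temperature; Q10 = 2 applied at run time. Units: ms^-1, ligand-dependent rates mM^-1 ms^-1.",
  "n_sites": 1,
  "states": [
    "R",
    "RG",
    "A"
  ],
  "n_bound": [
    0,
    1,
    1
  ],
  "resting_state": "R",
  "open_states": [],
  "active_states": [
    "A"
  ],
  "conductance_pS": 0,
  "erev_mV": 0,
  "q10": 2,
  "t_ref_K": 296,
  "transitions": [
    {
      "from": "R",
      "to": "RG",
      "rate": 1.0,
      "ligand": "glu"
    },
    {
      "from": "RG",
      "to": "R",
      "rate": 0.1,
      "ligand": "none"
    },
    {
      "from": "RG",
      "to": "A",
      "rate": 0.5,
      "ligand": "none"
    },
    {
      "from": "A",
      "to": "RG",
      "rate": 0.1,
      "ligand": "none"
    }
  ]
}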