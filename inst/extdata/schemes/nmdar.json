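{
  "name": "NMDAR generic two-agonist scheme (placeholder rates)",
  "comment": "Generic 5-state NMDAR: two sequential glutamate binding steps (slow unbinding), one open state, one desensitized state. Rates are round placeholder values referenced to room temperature; the engine applies Q10 = 2 scaling to the run temperature. Units: ms^-1, ligand-dependent rates mM^-1 ms^-1.",
  "n_sites": 2,
  "states": ["C0", "C1", "C2", "O", "D"],
  "n_bound": [0, 1, 2, 2, 2],
  "resting_state": "C0",
  "open_states": ["O"],
  "active_states": ["O"],
  "conductance_pS": 25,
  "erev_mV": 0,
  "q10": 2,
  "t_ref_K": 296,
  "transitions": [
    {"from": "C0", "to": "C1", "rate": 10.0,  "ligand": "glu"},
    {"from": "C1", "to": "C0", "rate": 0.08,  "ligand": "none"},
    {"from": "C1", "to": "C2", "rate": 5.0,   "ligand": "glu"},
    {"from": "C2", "to": "C1", "rate": 0.16,  "ligand": "none"},
    {"from": "C2", "to": "O",  "rate": 0.05,  "ligand": "none"},
    {"from": "O",  "to": "C2", "rate": 0.10,  "ligand": "none"},
    {"from": "C2", "to": "D",  "rate": 0.03,  "ligand": "none"},
    {"from": "D",  "to": "C2", "rate": 0.01,  "ligand": "none"}
  ]
}
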