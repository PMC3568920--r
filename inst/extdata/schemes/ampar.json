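{
  "name": "AMPAR generic fast scheme (placeholder rates)",
  "comment": "Generic 6-state AMPAR: two sequential glutamate binding steps, one open state, desensitized states off the mono- and double-liganded closed states. Rates are round, physiologically typical placeholder values for near-physiological temperature (fast mM-range activation, sub-ms deactivation, ms-range desensitization); replace with a published fit for quantitative receptor work. Units: ms^-1, ligand-dependent rates mM^-1 ms^-1.",
  "n_sites": 2,
  "states": ["C0", "C1", "C2", "O", "D1", "D2"],
  "n_bound": [0, 1, 2, 2, 1, 2],
  "resting_state": "C0",
  "open_states": ["O"],
  "active_states": ["O"],
  "conductance_pS": 10,
  "erev_mV": 0,
  "q10": 2,
  "t_ref_K": 307,
  "transitions": [
    {"from": "C0", "to": "C1", "rate": 20.0,  "ligand": "glu"},
    {"from": "C1", "to": "C0", "rate": 6.0,   "ligand": "none"},
    {"from": "C1", "to": "C2", "rate": 10.0,  "ligand": "glu"},
    {"from": "C2", "to": "C1", "rate": 12.0,  "ligand": "none"},
    {"from": "C2", "to": "O",  "rate": 6.0,   "ligand": "none"},
    {"from": "O",  "to": "C2", "rate": 3.0,   "ligand": "none"},
    {"from": "C1", "to": "D1", "rate": 0.3,   "ligand": "none"},
    {"from": "D1", "to": "C1", "rate": 0.05,  "ligand": "none"},
    {"from": "C2", "to": "D2", "rate": 2.0,   "ligand": "none"},
    {"from": "D2", "to": "C2", "rate": 0.05,  "ligand": "none"}
  ]
}
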