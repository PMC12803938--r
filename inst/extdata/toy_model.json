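{
  "metabolites": [
    {"id": "glc", "name": "D-glucose", "compartment": "c"},
    {"id": "g6p", "name": "glucose 6-phosphate", "compartment": "c"},
    {"id": "gap", "name": "glyceraldehyde 3-phosphate", "compartment": "c"},
    {"id": "pyr", "name": "pyruvate", "compartment": "c"},
    {"id": "accoa", "name": "acetyl-CoA", "compartment": "c"},
    {"id": "oaa", "name": "oxaloacetate", "compartment": "c"},
    {"id": "cit", "name": "citrate", "compartment": "c"},
    {"id": "icit", "name": "isocitrate", "compartment": "c"},
    {"id": "akg", "name": "2-oxoglutarate", "compartment": "c"},
    {"id": "ru5p", "name": "ribulose 5-phosphate", "compartment": "c"},
    {"id": "nadph", "name": "NADPH", "compartment": "c"},
    {"id": "co2", "name": "CO2", "compartment": "c"},
    {"id": "gln", "name": "L-glutamine", "compartment": "c"},
    {"id": "gly", "name": "glycine", "compartment": "c"},
    {"id": "ser", "name": "L-serine", "compartment": "c"},
    {"id": "arg", "name": "L-arginine", "compartment": "c"}
  ],
  "reactions": [
    {"id": "EX_glc", "stoichiometry": {"glc": -1}, "lb": -10, "ub": 1000, "subsystem": "Exchange", "is_exchange": true, "is_artificial": false},
    {"id": "EX_gln", "stoichiometry": {"gln": -1}, "lb": -5, "ub": 1000, "subsystem": "Exchange", "is_exchange": true, "is_artificial": false},
    {"id": "EX_gly", "stoichiometry": {"gly": -1}, "lb": -5, "ub": 1000, "subsystem": "Exchange", "is_exchange": true, "is_artificial": false},
    {"id": "EX_ser", "stoichiometry": {"ser": -1}, "lb": -5, "ub": 1000, "subsystem": "Exchange", "is_exchange": true, "is_artificial": false},
    {"id": "EX_arg", "stoichiometry": {"arg": -1}, "lb": -5, "ub": 1000, "subsystem": "Exchange", "is_exchange": true, "is_artificial": false},
    {"id": "EX_co2", "stoichiometry": {"co2": -1}, "lb": 0, "ub": 1000, "subsystem": "Exchange", "is_exchange": true, "is_artificial": false},
    {"id": "HEX1", "stoichiometry": {"glc": -1, "g6p": 1}, "lb": 0, "ub": 1000, "subsystem": "Glycolysis", "is_exchange": false, "is_artificial": false},
    {"id": "PGI_PFK", "stoichiometry": {"g6p": -1, "gap": 2}, "lb": 0, "ub": 1000, "subsystem": "Glycolysis", "is_exchange": false, "is_artificial": false},
    {"id": "PYK", "stoichiometry": {"gap": -1, "pyr": 1}, "lb": 0, "ub": 1000, "subsystem": "Glycolysis", "is_exchange": false, "is_artificial": false},
    {"id": "G6PD", "stoichiometry": {"g6p": -1, "ru5p": 1, "nadph": 2, "co2": 1}, "lb": 0, "ub": 1000, "subsystem": "Pentose phosphate pathway", "is_exchange": false, "is_artificial": false},
    {"id": "TKT", "stoichiometry": {"ru5p": -1, "gap": 1}, "lb": 0, "ub": 1000, "subsystem": "Pentose phosphate pathway", "is_exchange": false, "is_artificial": false},
    {"id": "PDH", "stoichiometry": {"pyr": -1, "accoa": 1, "co2": 1}, "lb": 0, "ub": 1000, "subsystem": "TCA cycle", "is_exchange": false, "is_artificial": false},
    {"id": "CS", "stoichiometry": {"accoa": -1, "oaa": -1, "cit": 1}, "lb": 0, "ub": 1000, "subsystem": "TCA cycle", "is_exchange": false, "is_artificial": false},
    {"id": "ICDH", "stoichiometry": {"cit": -1, "akg": 1, "co2": 1}, "lb": 0, "ub": 1000, "subsystem": "TCA cycle", "is_exchange": false, "is_artificial": false},
    {"id": "AKGD_MDH", "stoichiometry": {"akg": -1, "oaa": 1, "co2": 1}, "lb": 0, "ub": 1000, "subsystem": "TCA cycle", "is_exchange": false, "is_artificial": false},
    {"id": "PC", "stoichiometry": {"pyr": -1, "co2": -1, "oaa": 1}, "lb": 0, "ub": 1000, "subsystem": "TCA cycle", "is_exchange": false, "is_artificial": false},
    {"id": "GLS_GDH", "stoichiometry": {"gln": -1, "akg": 1}, "lb": 0, "ub": 1000, "subsystem": "Amino acid metabolism", "is_exchange": false, "is_artificial": false},
    {"id": "ACON_F", "stoichiometry": {"cit": -1, "icit": 1}, "lb": 0, "ub": 1000, "subsystem": "TCA cycle", "is_exchange": false, "is_artificial": false},
    {"id": "ACON_B", "stoichiometry": {"icit": -1, "cit": 1}, "lb": 0, "ub": 1000, "subsystem": "TCA cycle", "is_exchange": false, "is_artificial": false},
    {"id": "BIOMASS", "stoichiometry": {"pyr": -1, "ru5p": -0.5, "nadph": -1, "akg": -0.5, "gly": -0.2, "ser": -0.2, "arg": -0.1}, "lb": 0, "ub": 1000, "subsystem": "Biomass", "is_exchange": false, "is_artificial": false}
  ],
  "objective": {"BIOMASS": 1},
  "default_bound": 1000
}
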