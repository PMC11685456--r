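{
  "_comment": [
    "Approximate Hsp70 NBD lobe and helix annotations in mortalin",
    "(HSPA9) author numbering, for use with deposited mortalin-GrpEL1",
    "models. Derived from canonical DnaK lobe definitions shifted by",
    "the DnaK K250 -> mortalin K316 correspondence (+66). These",
    "boundaries are editable: rotation and displacement measurements",
    "depend on them and published analyses do not state exact spans.",
    "Chain ids follow the common deposition layout (mortalin chain A,",
    "GrpEL1 protomers B and C); edit to match the model in hand."
  ],
  "numbering": "author (mortalin / HSPA9)",
  "domains": {
    "lobe_IA": {"chain": "A", "ranges": [[67, 105], [182, 254], [427, 449]]},
    "lobe_IB": {"chain": "A", "ranges": [[106, 181]]},
    "lobe_IIA": {"chain": "A", "ranges": [[255, 294], [373, 426]]},
    "lobe_IIB": {"chain": "A", "ranges": [[295, 372]]},
    "iib_inward_helix": {"chain": "A", "ranges": [[310, 326]]},
    "nbd": {"chain": "A", "ranges": [[46, 431]]},
    "sbd_beta": {"chain": "A", "ranges": [[440, 555]]},
    "sbd_alpha_lid": {"chain": "A", "ranges": [[556, 639]]},
    "sbd_alpha_beta": {"chain": "A", "ranges": [[440, 639]]},
    "grpel1a_beta_wing": {"chain": "B", "ranges": [[160, 217]]},
    "grpel1b_beta_wing": {"chain": "C", "ranges": [[160, 217]]},
    "grpel1_stalk_a": {"chain": "B", "ranges": [[59, 136]]},
    "grpel1_stalk_b": {"chain": "C", "ranges": [[59, 136]]}
  }
}
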