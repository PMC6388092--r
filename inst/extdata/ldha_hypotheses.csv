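ligand_id,hypothesis,state,energy,unit
compound-1-ring,chair,bound,0,kcal_per_mol
compound-1-ring,boat,bound,10,kcal_per_mol
compound-1-ring,chair,free,0,kcal_per_mol
compound-1-ring,boat,free,9,kcal_per_mol
compound-2-phenyl,pseudo_axial,bound,0,kcal_per_mol
compound-2-phenyl,pseudo_equatorial,bound,8,kcal_per_mol
compound-2-phenyl,pseudo_axial,free,0,kcal_per_mol
compound-2-phenyl,pseudo_equatorial,free,0.1,kcal_per_mol
compound-2-oxygen,deposited_position,bound,0,kcal_per_mol
compound-2-oxygen,flipped_position,bound,0.2,kcal_per_mol
compound-3-phenyl,axial,bound,0,kcal_per_mol
compound-3-phenyl,equatorial,bound,4,kcal_per_mol
compound-3-phenyl,axial,free,0.6,kcal_per_mol
compound-3-phenyl,equatorial,free,0,kcal_per_mol
compound-11-pyridine,deposited_orientation,bound,0,kcal_per_mol
compound-11-pyridine,flipped_orientation,bound,4,kcal_per_mol
compound-12-ring,pseudo_axial,bound,0,kcal_per_mol
compound-12-ring,pseudo_equatorial,bound,5,kcal_per_mol
compound-12-ring,pseudo_axial,free,0,kcal_per_mol
compound-12-ring,pseudo_equatorial,free,0.4,kcal_per_mol
compound-12-nh,opposite_asn137,bound,0,kcal_per_mol
compound-12-nh,adjacent_asn137,bound,1,kcal_per_mol
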