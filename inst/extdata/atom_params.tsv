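# Heavy-atom (element-level) parameters for the desk energy backend and SASA.
# radius      = Lennard-Jones rmin/2 (Angstrom)
# well_depth  = Lennard-Jones epsilon (energy units)
# solvation_dG= Lazaridis-Karplus-style transfer free energy (negative =
#               hydrophobic, burial favourable)
# volume      = atomic volume used by the gaussian-exclusion solvation (A^3)
# sasa_radius = van der Waals radius used for surface area (Bondi-type values)
# Values are generic literature-magnitude parameters for a heavy-atom-only
# approximate force field; they do not reproduce any licensed parameter set.
atom_type	radius	well_depth	solvation_dG	volume	sasa_radius
C	1.95	0.105	-0.60	14.7	1.70
N	1.75	0.170	1.50	11.2	1.55
O	1.60	0.210	1.60	10.8	1.52
S	2.00	0.250	-0.45	14.7	1.80
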