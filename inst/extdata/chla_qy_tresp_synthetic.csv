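# SYNTHETIC stand-in Qy transition-charge set for chlorophyll a (residue CLA)
# Constructed for this package: zero transition monopole, dipole along the
# NB-ND macrocycle axis (the Qy polarization direction), macrocycle atoms only
# (the phytyl tail carries no transition charge). NOT the published gas-phase
# TrESP set; all workflows rescale charges to an effective Qy dipole
# (4.3 D by default), so only the charge pattern, not its scale, matters here.
atom_name,charge_e
NB,0.200
ND,-0.200
NA,0.010
NC,0.010
C1A,-0.010
C1C,-0.010
C1B,0.060
C4B,0.060
C1D,-0.060
C4D,-0.060
C2B,0.030
C3B,0.030
C2D,-0.030
C3D,-0.030
CHB,0.040
CHD,-0.040
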