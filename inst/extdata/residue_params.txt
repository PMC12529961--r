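# Per-residue parameters: one-letter code, three-letter code,
# vdW diameter sigma_i (Angstrom), relative surface frequency f_i.
# sigma: transcribed coarse-grained bead diameters; surface_freq: approximate
# surface amino-acid composition of globular proteins (sums to 1).
# Both replaceable via the `residue_table` argument of mj_model().
code code3 sigma surface_freq
C CYS 5.480 0.019
M MET 6.180 0.022
F PHE 6.360 0.039
I ILE 6.180 0.051
L LEU 6.180 0.091
V VAL 5.860 0.062
W TRP 6.780 0.014
Y TYR 6.460 0.032
A ALA 5.040 0.078
G GLY 4.500 0.074
T THR 5.620 0.058
S SER 5.180 0.071
N ASN 5.680 0.045
Q GLN 6.020 0.043
D ASP 5.580 0.054
E GLU 5.920 0.063
H HIS 6.080 0.022
R ARG 6.560 0.051
K LYS 6.360 0.059
P PRO 5.560 0.052
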