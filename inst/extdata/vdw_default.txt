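# Element-level nonbonded parameters (CHARMM-style convention).
# radius: van der Waals radius r_i in Angstrom (half the pair minimum-energy
#         distance; pairs combine as r_ij = r_i + r_j)
# epsilon: well depth in kcal/mol (pairs combine as eps_ij = sqrt(eps_i eps_j))
# Columns: element radius epsilon   (or: element atom_name radius epsilon)
H   1.32  0.030
C   2.00  0.110
N   1.85  0.200
O   1.70  0.120
S   2.00  0.450
P   2.15  0.585
SE  2.10  0.470
MG  0.79  0.015
ZN  1.09  0.250
FE  0.65  0.010
NA  1.36  0.047
K   1.76  0.087
CL  2.27  0.150
CA  1.37  0.120
MN  0.80  0.015
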