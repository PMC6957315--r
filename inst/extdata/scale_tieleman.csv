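# Side-chain analog water-to-DOPC-bilayer-center transfer free energies
# (kcal/mol) from atomistic PMF calculations (MacCallum, Bennett & Tieleman,
# Biophys J 2008). Positive = prefers water. His, Gly and Pro lack values in
# this scale and are deliberately absent here; the solvation ledger fills
# them from the Fleming scale. Values transcribed from the publication.
residue_type,s_transfer
ALA,-2.01
ARG,3.36
ASN,1.73
ASP,5.33
CYS,-3.11
GLN,1.52
GLU,4.53
ILE,-5.04
LEU,-4.92
LYS,2.51
MET,-3.93
PHE,-5.18
SER,-0.91
THR,-1.59
TRP,-2.71
TYR,-1.70
VAL,-4.15
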