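# Side-chain water-to-bilayer transfer free energies (kcal/mol), whole-protein
# hydrophobicity scale measured by OMPLA folding stability (Moon & Fleming,
# PNAS 2011). Positive values = residue prefers water; negative = prefers the
# bilayer. Values transcribed from the publication.
residue_type,s_transfer
ALA,0.00
ARG,2.57
ASN,1.01
ASP,1.23
CYS,-0.49
GLN,0.58
GLU,2.02
GLY,1.15
HIS,2.05
ILE,-1.56
LEU,-1.81
LYS,2.80
MET,-0.76
PHE,-2.20
PRO,1.52
SER,0.11
THR,0.27
TRP,-2.09
TYR,-0.71
VAL,-0.78
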