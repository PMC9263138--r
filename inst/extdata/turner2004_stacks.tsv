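# RNA nearest-neighbor helix stacking free energies, 37 C, kcal/mol.
# Turner 2004 parameter set (values as distributed with ViennaRNA 2.7.2,
# rna_turner2004.par "stack" table; identical to the NNDB Turner 2004
# Watson-Crick and G:U stacks at 0.1 kcal/mol rounding).
# Lookup: stack of top dinucleotide s1 s2 (5p->3p) over bottom b1 b2
# (3p->5p) = row with pair5p = s1:b1 and pair3p = b2:s2.
# checksum_x100: -5720
pair5p	pair3p	dg_kcal
CG	CG	-2.40
GC	CG	-3.30
GU	CG	-2.10
UG	CG	-1.40
AU	CG	-2.10
UA	CG	-2.10
CG	GC	-3.30
GC	GC	-3.40
GU	GC	-2.50
UG	GC	-1.50
AU	GC	-2.20
UA	GC	-2.40
CG	GU	-2.10
GC	GU	-2.50
GU	GU	1.30
UG	GU	-0.50
AU	GU	-1.40
UA	GU	-1.30
CG	UG	-1.40
GC	UG	-1.50
GU	UG	-0.50
UG	UG	0.30
AU	UG	-0.60
UA	UG	-1.00
CG	AU	-2.10
GC	AU	-2.20
GU	AU	-1.40
UG	AU	-0.60
AU	AU	-1.10
UA	AU	-0.90
CG	UA	-2.10
GC	UA	-2.40
GU	UA	-1.30
UG	UA	-1.00
AU	UA	-0.90
UA	UA	-1.30
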