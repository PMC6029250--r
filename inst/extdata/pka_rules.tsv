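# Ionizable-group rule table: SMARTS (first pattern atom = ionizable atom),
# representative pKa, acid/base flag.  Patterns match only neutral groups so
# protonation-state assignment is idempotent at a fixed pH.
name	smarts	pka	type
sulfonic_acid	[OX2H1;+0][SX4](=[OX1])=[OX1]	-1.0	acid
carboxylic_acid	[OX2H1;+0][CX3]=[OX1]	4.8	acid
phosphate_oh	[OX2H1;+0][PX4]=[OX1]	6.5	acid
thiol	[SX2H1;+0][CX4]	8.3	acid
phenol	[OX2H1;+0]c	10.0	acid
aromatic_thiol	[SX2H1;+0]c	6.6	acid
guanidine	[NX2H1;+0]=[CX3]([NX3])[NX3]	12.5	base
amidine	[NX2H1;+0]=[CX3][NX3H2]	11.5	base
primary_amine	[NX3H2;+0][CX4]	10.6	base
secondary_amine	[NX3H1;+0]([CX4])[CX4]	10.7	base
tertiary_amine	[NX3H0;+0]([CX4])([CX4])[CX4]	9.8	base
aniline	[NX3H2;+0]c	4.6	base
imidazole_n	[nX2;+0;r5]	6.0	base
pyridine_n	[nX2;+0;r6]	5.2	base
hydroxylamine_n	[NX3H2;+0][OX2]	6.0	base
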