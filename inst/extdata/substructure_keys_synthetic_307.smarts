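# Synthetic substructure key set (307 SMARTS patterns, one per line).
# This is a package-curated stand-in for a 307-key structural fingerprint
# dictionary: curated functional groups relevant to biochemistry plus
# systematic element/bond/ring and H-count/degree/charge patterns, all
# expressed in the SMARTS subset this package matches.  Bit i of the
# substructure fingerprint corresponds to line i (comments excluded).
[CX3](=O)[OX2H1]
[CX3](=O)[O-]
[CX3](=[OX1])[OX2][#6]
[CX3H1]=O
[CX3](=O)[#6]
[CX3](=O)[NX3]
[CX3](=O)[NX3H2]
[CX3](=O)[NX3H1][#6]
[NX3H2][CX4]
[NX3H1]([CX4])[CX4]
[NX3]([CX4])([CX4])[CX4]
[NX4+]
[NX3+0][CX3]=[OX1]
[NX2]=[CX3]
[NX1]#[CX2]
[NX3][CX3](=[NX2])[NX3]
[NX3H1]c
[NX3H2]c
[OX2H1][CX4]
[OX2H1][CX4H2]
[OX2H1][CX4H1]
[OX2H1][CX4X4]
[OX2]([#6])[#6]
[OX2H1]c
[OX2H1][CX3]=[CX3]
[SX2H1]
[SX2]([#6])[#6]
[SX2][SX2]
[SX4](=O)(=O)
[SX3]=[OX1]
[SX4](=[OX1])(=[OX1])[OX2H1]
[SX4](=[OX1])(=[OX1])[NX3]
[PX4](=[OX1])([OX2])[OX2]
[PX4](=[OX1])([OX2H1])[OX2H1]
[PX4](=[OX1])([O-])[OX2]
[OX2]([PX4])[PX4]
[OX2]([CX4])[PX4]
[CX3]=[CX3]
[CX2]#[CX2]
[CX3]=[CX3][CX3]=[CX3]
[CX3](=[OX1])[CX3]=[CX3]
[CX4][F]
[CX4][Cl]
[CX4][Br]
[CX4][I]
c[F]
c[Cl]
c[Br]
c[I]
[OX2H1][CX3]=[OX1]
[NX3][NX3]
[NX2]=[NX2]
[NX3][NX2]=[NX1]
[OX2][NX2]=[OX1]
[NX3](=[OX1])=[OX1]
[NX3+](=[OX1])[O-]
[CX3](=[OX1])[OX2][CX3](=[OX1])
[CX4]([OX2H1])[CX3](=O)[OX2H1]
[CX4]([NX3H2])[CX3](=O)[OX2H1]
[CX4]([NX3H2])[CX3](=O)[O-]
[CX4]([NX4+])[CX3](=O)[O-]
[SX2H1][CX4]
[SX2][CX4][CX4][NX3]
[OX2H1][CX4][CX4][NX3]
[OX2H1][CX4][CX3](=O)
[CX3](=O)[CX3](=O)
[CX3](=O)[CX4][CX3](=O)
[OX2H1][CX4][CX4][OX2H1]
[CX4]([OX2H1])([OX2H1])
[CX4]([OX2])([OX2])[OX2]
c1ccccc1
c1ccncc1
c1cccnc1
c1ccoc1
c1ccsc1
c1cc[nH]c1
c1cnccn1
c1cncnc1
c1ncncn1
c1ccc2ccccc2c1
C1CCCCC1
C1CCCC1
C1CCC1
C1CC1
C1CCOC1
C1CCOCC1
C1CCNC1
C1CCNCC1
C1CCSC1
O1CCOCC1
C1OCCO1
[cX3][OX2H1]
[cX3][NX3H2]
[cX3][CX3](=O)[OX2H1]
[cX3][CX3H1]=O
[cX3][SX2H1]
[cX3][NX3+](=[OX1])[O-]
[n;H1]
[nX2]
[o]
[sX2]
[c]([c])([c])[c]
[CX4H3][NX3]
[CX4H3][OX2]
[CX4H3][SX2]
[CX4H3]c
[CX4H3][CX3]=O
[#6][#6]
[#6][#7]
[#6][#8]
[#6][#16]
[#6][#15]
[#6][#9]
[#6][#17]
[#6][#35]
[#6][#53]
[#7][#7]
[#7][#8]
[#7][#16]
[#8][#15]
[#8][#16]
[#16][#16]
[#7][#15]
[#8][#8]
[#6]=[#6]
[#6]=[#7]
[#6]=[#8]
[#6]=[#16]
[#7]=[#7]
[#7]=[#8]
[#16]=[#8]
[#15]=[#8]
[#6]#[#6]
[#6]#[#7]
[CX4H3]
[CX4H2]
[CX4H1]
[CX4H0]
[CX3H2]
[CX3H1]
[CX3H0]
[CX2H1]
[CX2H0]
[NX3H2]
[NX3H1]
[NX3H0]
[OX2H1]
[OX2H0]
[SX2H0]
[CX4]
[CX3]
[CX2]
[NX3]
[NX2]
[NX1]
[OX2]
[OX1]
[C+0;X4;H2;R]
[C;R0;X4]
[c;R]
[C;R]
[N;R]
[n;R]
[O;R]
[o;R]
[S;R]
[s;R]
[P;X4]
[N+]
[N-]
[O-]
[C-]
[S-]
[O+]
[#6;+]
[r3]
[r4]
[r5]
[r6]
[r7]
[C;r5]
[C;r6]
[N;r5]
[N;r6]
[O;r5]
[O;r6]
[c;r5]
[n;r6]
[n;r5]
[CX4][CX4]
[CX4][CX4][CX4]
[CX4][CX4][CX4][CX4]
[CX4][CX4][CX4][CX4][CX4]
[CX4]([CX4])([CX4])[CX4]
[CX4]([CX4])([CX4])([CX4])[CX4]
[CX4H2][CX4H2][CX4H2]
[CX4H3][CX4H1][CX4H3]
[CX4H3][CX4]([CX4H3])[CX4H3]
[#6][#8][#6][#8][#6]
[#6][#7][#6][#7][#6]
[#8][#6][#6][#8]
[#7][#6][#6][#7]
[#7][#6][#6][#8]
[#16][#6][#6][#7]
[#6][#6](=O)[#7][#6][#6](=O)
[OX2H1][#6][#6][#6][OX2H1]
[NX3][#6][#6][#6][NX3]
[#6]=[#6][#6]=[#6]
[#6]=[#6][#6](=O)
[#8]=[#6][#8]
[#7][#6]=[#8]
[#7][#6]=[#16]
[#6]=[#7][#7]
[#6][#16][#6][#6]
[#6][#8][#6][#6]
[#6][#7][#6][#6]
c[CX4]
c[CX3]=O
c[OX2][CX4]
c[NX3][CX4]
c[SX2][CX4]
cc
ccc
cccc
c[cX3][cX3]c
cncn
cnc
ncn
c[nH1]c
coc
csc
c1ccc(cc1)[OX2H1]
c1ccc(cc1)[NX3H2]
c1ccc(cc1)[CX4]
c1ccc(cc1)[F,Cl,Br,I]
c1ccc2c(c1)cccc2
[cX3]1[cX3][cX3][cX3][cX3][cX3]1[CX3](=O)
[OX2H1][PX4]
[OX2][SX4]
[NX3][SX4]
[NX3][PX4]
[#6]=[#6][OX2H1]
[#6]=[#6][NX3]
[#6]=[#6][OX2][#6]
[CX4]([F])([F])[F]
[CX4]([Cl])[Cl]
[#6](=O)[F,Cl,Br,I]
[NX2]=[CX3][NX3]
[OX1]=[CX3][NX3][CX3]=[OX1]
[SX2][CX3]=[OX1]
[#6][#6](=O)[#8][#6]
[OX2H1][CX4][CX4][CX4][CX3](=O)
[NX3H2][CX4][CX4][CX3](=O)
[#7]#[#6][#6]
[#8][#6]=[#7]
[#16]=[#6][#7]
[#6][#6]([#6])=[#8]
[CX4][OX2][CX3](=[OX1])[CX4]
[CX4][NX3][CX3](=[OX1])[CX4]
[CX3](=[OX1])([NX3])[NX3]
[NX3][CX3](=[SX1])[NX3]
[OX2H1][c;r6][c;r6][OX2H1]
[NX3H2][c;r6][c;r6][OX2H1]
[#6][#6][#6]
[#6][#6][#7]
[#6][#6][#8]
[#6][#7][#6]
[#6][#7][#7]
[#6][#7][#8]
[#6][#8][#6]
[#6][#8][#7]
[#6][#8][#8]
[#6][#16][#6]
[#6][#16][#7]
[#6][#16][#8]
[#7][#6][#7]
[#7][#6][#8]
[#7][#7][#7]
[#7][#7][#8]
[#7][#8][#7]
[#7][#8][#8]
[#7][#16][#7]
[#7][#16][#8]
[#8][#6][#8]
[#8][#7][#8]
[#8][#8][#8]
[#8][#16][#8]
[F][CX4][F]
[Cl][CX4][Cl]
[CX4]([F])[Cl]
[c]([F])
[c]([Cl])c[Cl]
[CX3](=O)[CX4][F,Cl,Br,I]
[CX4]([Br])[CX4]
[CX4]([I])[CX4]
[CX4]([OX2H1])[CX4][OX2H1]
[CX3](=[OX1])[CX4][OX2H1]
[CX3](=[OX1])[CX4][NX3]
[CX4]([SX2H1])[CX3](=O)
[PX4](=[OX1])([OX2H1])([OX2H1])[OX2H1]
[PX4](=[OX1])([O-])([O-])[OX2]
[SX4](=[OX1])(=[OX1])([OX2H1])[#6]
[SX4](=[OX1])(=[OX1])([O-])[#6]
[CX4H2]([NX3])[CX3](=O)
[NX3H1][NX3H1]
[OX2][OX2H1]
[CX2]#[CX2][CX4]
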