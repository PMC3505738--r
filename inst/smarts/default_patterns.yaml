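# Default pharmacophore typing patterns for usrcatkit.
#
# Four feature classes, each a list of SMARTS; an atom belongs to a class if
# it matches at least one pattern of that class. Classes may overlap (an
# hydroxyl oxygen is both donor and acceptor). Users may override this file
# with their own definitions (see load_pattern_set / the --smarts CLI flag).
hydrophobic:
  - "[c,C&!$(C=[O,N,S])&!$(C#N)]"
  - "[F,Cl,Br,I]"
aromatic:
  - "[a]"
donor:
  - "[#7;H1,H2,H3;!$([nX3])]"
  - "[#8;H1]"
acceptor:
  - "[N;!$([N+]);!$([NX3][CX3]=[OX1]);!$([nX3H1])]"
  - "[O;!$([OX2H0][CX3]=[OX1])]"
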