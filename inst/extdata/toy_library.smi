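CC(OC)CCCCCC	CMPD00001
c1c(C=CC)c(N)c(N(C)C=O)cn1	CMPD00002
CCCCCC(C(=O)O)C(N)C	CMPD00003
C1C(N(C)C=O)C(S(=O)(=O)N)CCC1	CMPD00004
c1ccccc1	CMPD00005
c1c(N(C)C=O)cccc1	CMPD00006
CCCCCCCC	CMPD00007
c1c(N)cccn1	CMPD00008
CCCCCCC(Cl)C	CMPD00009
c1ccc(Cl)cn1	CMPD00010
CCCCCCC(C(F)(F)F)C	CMPD00011
CCCCCCCC	CMPD00012
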