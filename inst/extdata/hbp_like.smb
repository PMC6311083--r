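# Nine-entity Boolean stand-in for the hexosamine biosynthetic pathway
# intersection with PI3K/Myc and P53-MDM2 signalling. SYNTHETIC topology:
# attested motifs (P53-MDM2 negative feedback, CMyc -> OGT, OGA -| OGT,
# OGT -> CMyc loop) plus invented wiring for the remaining entities.
VAR
NFkB = 0..1 ;
P21 = 0..1 ;
FoXM1 = 0..1 ;
PI3K = 0..1 ;
P53 = 0..1 ;
MDM2 = 0..1 ;
OGT = 0..1 ;
OGA = 0..1 ;
CMyc = 0..1 ;
REG
P53 [1] -> + MDM2 ;
MDM2 [1] -> - P53 ;
CMyc [1] -> + OGT ;
OGA [1] -> - OGT ;
OGT [1] -> + CMyc ;
NFkB [1] -> + PI3K ;
PI3K [1] -> + FoXM1 ;
FoXM1 [1] -> - P21 ;
CTL
(OGT=1,OGA=0) -> EF(AG(OGT=1,OGA=0,PI3K=1,FoXM1=1,P21=0,CMyc=1)) ;
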