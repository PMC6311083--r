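# Two-gene mucus-production network of Pseudomonas aeruginosa.
# x = sigma factor AlgU (three levels), y = its anti-sigma-factor inhibitor.
# Thresholds and observations reconstruct the published figure.
VAR
x = 0..2 ;
y = 0..1 ;
REG
x [2] -> + x ;   # self-activation at the top level
x [1] -> + y ;   # AlgU induces its own inhibitor
y [1] -> - x ;   # the inhibitor represses AlgU
CTL
# normal response: from rest, AlgU never over-expresses
(x=0 & y=0) -> AG(!(x=2)) ;
# pathogenic response: the over-expressed state is stable
(x=2 & y=1) -> AG(x=2) ;
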