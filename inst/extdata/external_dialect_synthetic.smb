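# SYNTHETIC sample of an externally produced model file mixing this
# package's grammar with foreign directives, for exercising the
# compatibility reader (compat = TRUE): unknown statements are reported,
# recognized ones are loaded.
VAR
x = 0..1 ;
y = 0..1 ;
REG
x [1] -> + y ;
y : x >= 1 ;
CTL
INIT x = 0 ;
EF(y=1) ;
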