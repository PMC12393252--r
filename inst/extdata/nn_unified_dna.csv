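# Unified DNA/DNA nearest-neighbor parameters (SantaLucia unified set).
# dh in kcal/mol, ds in cal/(mol K). Stacks keyed by the 5'->3' dinucleotide
# of one strand; reverse-complement dinucleotides share one parameter.
# 'initiation' is applied once per duplex; 'terminal_at' once per duplex end
# whose closing pair is A.T.
term,dh,ds
AA,-7.9,-22.2
TT,-7.9,-22.2
AT,-7.2,-20.4
TA,-7.2,-21.3
CA,-8.5,-22.7
TG,-8.5,-22.7
GT,-8.4,-22.4
AC,-8.4,-22.4
CT,-7.8,-21.0
AG,-7.8,-21.0
GA,-8.2,-22.2
TC,-8.2,-22.2
CG,-10.6,-27.2
GC,-9.8,-24.4
GG,-8.0,-19.9
CC,-8.0,-19.9
initiation,0.2,-5.7
terminal_at,2.2,6.9
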