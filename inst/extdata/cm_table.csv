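# Revised NIOSH Lifting Equation coupling multiplier (CM), metric version 1991.
# v_low: V < 75 cm, v_high: V >= 75 cm.
coupling,v_low,v_high
good,1.00,1.00
fair,0.95,1.00
poor,0.90,0.90
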