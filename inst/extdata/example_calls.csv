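compound,tgx_minus,tgx_plus,mn_minus,mn_plus,moa_minus,moa_plus
cpd01,-,+,+,+,-,-
cpd02,,+,+,+,-,C
cpd03,,+,+,+,C,C
cpd04,,+,+,+,C,C/A
cpd05,,+,+,+,C,C
cpd06,,-,+,+,-,-
cpd07,+,+,+,+,C,C
cpd08,-,+,-,+,-,-
cpd09,+,+,+,+,C,C
cpd10,-,-,-,+,-,-
ctrl_pos_a,+,,+,+,C,C
ctrl_pos_b,,+,+,+,-,C
ctrl_neg,-,-,-,-,-,-
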