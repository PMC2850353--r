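(t2:0.15,t9:0.15,((((t1:0.15,(t4:0.15,t7:0.15):0.15):0.15,t8:0.15):0.15,(t5:0.15,t3:0.15):0.15):0.15,t6:0.15):0.15);
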