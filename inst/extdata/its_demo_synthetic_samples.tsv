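id	taxon	group
fic_r1	fic	parentA_diploid
sue_r4	sue	parentA_diploid
stc_r7	stc	parentB_tetraploid
alb_r12	alb	hybrid_hexaploid
alb_r15	alb	hybrid_hexaploid
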