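# Parents
*	Homer Simpson
*C	Marge Simpson
# Offspring
*o1	Bart Simpson
*a2	Lisa Simpson
*a3	Maggie Simpson
# Grandpas
*P	Abe Simpson
*M	Mona Simpson
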