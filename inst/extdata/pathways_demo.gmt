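EMT_CORE_SWITCH	mutual-inhibition core of the EMT circuit	SNAIL1	MIR34	ZEB1	MIR200
EPITHELIAL_MARKERS	epithelial identity genes	CDH1	MIR200	MIR34
MESENCHYMAL_MARKERS	mesenchymal identity genes	VIM	ZEB1	SNAIL1
SIGNAL_RESPONSE	external-signal responsive genes	TWIST1	SNAIL1	ZEB1
MICRO_RNAS	microRNA species in the circuit	MIR34	MIR200
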