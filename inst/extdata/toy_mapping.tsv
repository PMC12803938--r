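measured_name	model_metabolite_id
glucose	glc
glutamine	gln
glycine	gly
serine	ser
arginine	arg
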