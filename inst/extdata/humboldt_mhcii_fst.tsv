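locality	Punta San Juan	Pan de Azucar Island	Pajaro Island	Cachagua Island
Punta San Juan	0	0.956	0.959	0.955
Pan de Azucar Island	0.956	0	0.079	0.110
Pajaro Island	0.959	0.079	0	0.023
Cachagua Island	0.955	0.110	0.023	0
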