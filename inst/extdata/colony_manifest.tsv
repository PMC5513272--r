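barcode	locality	latitude	longitude	country	species	n_individuals
BC1	Punta San Juan	15°22′ S	75°12′ W	Peru	S. humboldti	25
BC2	Pan de Azucar Island	26°09′ S	70°41′ W	Chile	S. humboldti	25
BC3	Pajaro Island	29°35′ S	71°32′ W	Chile	S. humboldti	25
BC4	Cachagua Island	32°35′ S	71°27′ W	Chile	S. humboldti	25
BC5	Puñihuil Island	41°55′ S	74°02′ W	Chile	S. magellanicus	25
BC6	Magdalena Island	52°55′ S	70°34′ W	Chile	S. magellanicus	25
BC7	Puerto Deseado	47°54′ S	65°42′ W	Argentina	S. magellanicus	25
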