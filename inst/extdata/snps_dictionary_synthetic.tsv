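rsid	alias
rs2285666	c.439+4G>A
rs12329760	p.V160M
rs4646116	p.K26R
rs11385942	-
rs12252	-
rs1244687367	-
rs143936283	p.E329G
rs73635825	p.S19P
rs8176746	-
rs8176719	-
rs10735079	-
rs2236757	-
rs74956615	-
rs2109069	-
rs1131454	p.R130H
rs10774671	-
rs6489867	-
rs4767027	-
rs5743810	-
rs3775291	-
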