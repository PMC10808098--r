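Locus	Rate
DYS19	0.0021
DYS389I	0.0026
DYS389II	0.0034
DYS390	0.0022
DYS391	0.0026
DYS392	0.0005
DYS393	0.0011
DYS437	0.0013
DYS438	0.0004
DYS439	0.0047
DYS448	0.0016
DYS456	0.0042
DYS458	0.0063
DYS635	0.0037
GATAH4	0.0028
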