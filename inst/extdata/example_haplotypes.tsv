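SampleID	Population	DYS19	DYS385a	DYS385b	DYS389I	DYS389II	DYS390	DYS391	DYS392	DYS393	DYS437	DYS438	DYS439	DYS448	DYS456	DYS458	DYS635	GATAH4
IS01	IslandA	15	14	18	13	29	24	10	14	12	14	10	12	19	15	17	21	11
IS02	IslandA	15	14	18	13	29	24	10	14	12	14	10	12	19	15	17	21	11
IS03	IslandA	15	14	18	13	29	24	10	14	12	14	10	13	19	15	17	21	11
IS04	IslandA	15	14	17	13	30	24	10	14	12	14	10	12	19	15	18	21	11
IS05	IslandA	15	14	18	13	29	24	11	14	12	14	10	12	19	16	17	21	11
MA01	IslandB	16	14	18	14	30	24	10	14	13	14	10	12	20	15	19	21	12
MA02	IslandB	16	14	18	14	30	24	10	14	13	14	10	12	20	15	19	22	12
MA03	IslandB	16	13	18	14	30	25	10	14	13	14	10	12	20	15	19	22	12
MA04	IslandB	16	14	18	14	30	24	10		13	14	10	12	20	15	19	22	12
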