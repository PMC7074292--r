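accession	family	organism	genome_size_bp	path
AE001273.1	Chlamydiales	Chlamydia trachomatis D/UW-3/CX	1042519	AE001273.1.fasta
AE002160.2	Chlamydiales	Chlamydia muridarum Nigg	1072950	AE002160.2.fasta
AE009440.1	Chlamydiales	Chlamydophila pneumoniae TW-183	1225935	AE009440.1.fasta
AE015925.1	Chlamydiales	Chlamydophila caviae GPIC	1173390	AE015925.1.fasta
AP006861.1	Chlamydiales	Chlamydia felis Fe/C-56	1166239	AP006861.1.fasta
CP002549.1	Chlamydiales	Chlamydophila psittaci 6BC	1171660	CP002549.1.fasta
CP002608.1	Chlamydiales	Chlamydophila pecorum E58	1106197	CP002608.1.fasta
CP006571.1	Chlamydiales	Chlamydia avium 10DC88	1041170	CP006571.1.fasta
CP015840.1	Chlamydiales	Chlamydia gallinacea 08-1274/3	1059583	CP015840.1.fasta
CR848038.1	Chlamydiales	Chlamydophila abortus strain S26/3	1144377	CR848038.1.fasta
BA000031.2	Vibrionaceae	Vibrio parahaemolyticus RIMD 2210633	3288558	BA000031.2.fasta
BA000037.2	Vibrionaceae	Vibrio vulnificus YJ016	3354505	BA000037.2.fasta
CP000020.2	Vibrionaceae	Vibrio fischeri ES114	2897536	CP000020.2.fasta
CP000626.1	Vibrionaceae	Vibrio cholerae O395	1108250	CP000626.1.fasta
CP000789.1	Vibrionaceae	Vibrio harveyi ATCC BAA-1116	3765351	CP000789.1.fasta
CP002284.1	Vibrionaceae	Vibrio anguillarum 775	3063912	CP002284.1.fasta
CP002377.1	Vibrionaceae	Vibrio furnissii NCTC 11218	3294546	CP002377.1.fasta
CR354531.1	Vibrionaceae	Photobacterium profundum SS9	4085304	CR354531.1.fasta
FM178379.1	Vibrionaceae	Aliivibrio salmonicida LFI1238	3325165	FM178379.1.fasta
FM954972.2	Vibrionaceae	Vibrio splendidus LGP32	3299303	FM954972.2.fasta
AL590842.1	Yersiniaceae	Yersinia pestis CO92	4653728	AL590842.1.fasta
CP000720.1	Yersiniaceae	Yersinia pseudotuberculosis IP 31758	4723306	CP000720.1.fasta
CP000826.1	Yersiniaceae	Serratia proteamaculans 568	5448853	CP000826.1.fasta
CP002505.1	Yersiniaceae	Rahnella sp. Y9602	4864217	CP002505.1.fasta
CP002774.1	Yersiniaceae	Serratia sp. AS12	5443009	CP002774.1.fasta
CP006250.1	Yersiniaceae	Serratia plymuthica 4Rx13	5328010	CP006250.1.fasta
CP016940.1	Yersiniaceae	Yersinia enterocolitica strain YE5	4593248	CP016940.1.fasta
CP017236.1	Yersiniaceae	Yersinia ruckeri strain QMA0440 isolate 14/0165-5k	3856634	CP017236.1.fasta
HG738868.1	Yersiniaceae	Serratia marcescens SMB2099	5123091	HG738868.1.fasta
LN890288.1	Yersiniaceae	Serratia symbiotica strain STs	650317	LN890288.1.fasta
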