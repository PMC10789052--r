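site_id	population	protein_change	ac	an	af	control_ac	control_an	control_af	control_coverage	cscore	published_or	published_p
16:31469751:A:G	EUR	p.Thr12Ala	3	1510	0.0020	0	18978	0.0000	50	13.12	Inf	0.026
16:31470942:C:T	EUR	p.Pro128Ser	3	1450	0.0021	32	41112	0.0008	50	19.13	2.86	0.302
16:31473868:C:T	EUR	p.Arg429Cys	3	1494	0.0020	0	42506	0.0000	50	24.1	Inf	0.011
16:31477780:G:A	EUR	p.Arg888Gln	3	1470	0.0020	19	42368	0.0004	50	22.8	4.75	0.198
16:31470793:G:A	MEX	p.Arg78His	3	1500	0.0020	2	13094	0.0002	50	27.5	13.12	0.106
16:31470811:C:T	MEX	p.Ala84Val	3	1500	0.0020	13	14204	0.0009	50	13.5	2.19	0.384
16:31474085:G:A	MEX	p.Arg501Gln	3	1500	0.0020	3	17048	0.0002	50	21.2	11.39	0.109
16:31474132:G:A	MEX	p.Gly517Ser	3	1498	0.0020	2	17048	0.0001	50	23	17.15	0.083
16:31476020:C:T	MEX	p.Pro654Leu	3	1488	0.0020	7	16780	0.0004	50	20.6	4.92	0.205
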