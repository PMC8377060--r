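gene_id	fpkm_total_ctrl_1	fpkm_polysome_ctrl_1	fpkm_total_ko_1	fpkm_polysome_ko_1	fpkm_total_ctrl_2	fpkm_polysome_ctrl_2	fpkm_total_ko_2	fpkm_polysome_ko_2
gene_utr5_canonical_001	20.319225597454412	18.133321611483254	18.219599610126586	9.378268489985086	21.085905208389114	16.46317776192027	17.00534280156989	7.610455066683942
gene_utr5_bulge_001	18.06500994600611	26.013424699181986	17.727770897440916	10.22414402922575	16.73874102489013	26.849548149540155	17.638813784359552	9.707845308643133
gene_utr5_two_quartet_001	19.0717510393082	15.602269254523039	17.117050379497144	7.871491174238265	19.22865213732372	16.105448154020582	18.780586512736733	6.59878116098661
gene_cds_bound_001	24.46099315730731	15.61870251295842	19.75029230965061	18.40596441082588	18.206149526022976	17.02035019202517	19.598718297835834	17.846757870028956
gene_utr3_are_001	7.552327335934148	8.382663649763316	9.505652157673666	7.293938102435946	7.239496430858133	6.9002849854915205	7.629845305002866	8.727386712804108
gene_control_001	59.96912327327933	65.42140821646628	51.10385954205576	72.2143920137351	42.330149169172266	64.95399975783585	64.48589679660401	68.5401566118553
gene_control_002	82.5292323441713	76.72085560638844	74.03341934422495	84.74229611130511	78.80345624149165	83.48256874670574	69.7519773264521	84.71958809220548
gene_control_003	3.346903482306441	4.402514548509724	3.3703794707478387	5.112228730437589	3.8241503011910054	5.239187136416083	4.275853182785341	5.322605997732778
gene_control_004	31.7482734753088	36.63154307720135	31.712217627882815	33.72376003181947	35.16463821874399	38.36070190923518	37.44776741927113	39.85473366487662
gene_control_005	174.89291117035276	144.16565992099265	166.8123454330255	159.68035954525863	148.28598311008608	120.45858473639758	156.2718290679231	125.88533788065816
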