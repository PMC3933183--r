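matrix	n_char	scheme	n_partitions	lnl	aicc
ntAll	58347	OnePart	1	-3135739.544116	6272952.811161
ntAll	58347	CodonPart	3	-3099273.099639	6200056.468462
ntAll	58347	GenePart	78	-3120195.077316	6243312.241766
ntAll	58347	CodonGenePart	234	-3076219.426792	6158418.926624
RY	58347	OnePart	1	-1239354.453402	2480173.246480
RY	58347	CodonPart	3	-1235533.368070	2472537.854401
RY	58347	GenePart	78	-1234706.178899	2471197.311314
RY	58347	CodonGenePart	234	-1228081.159986	2458600.459411
ntNo3rd	38898	OnePart	1	-1387913.034830	2777313.721117
ntNo3rd	38898	CodonPart	2	-1385570.086154	2772645.570816
ntNo3rd	38898	GenePart	78	-1376158.263023	2755293.787916
ntNo3rd	38898	CodonGenePart	156	-1371218.716450	2746987.704270
AA	19449	OnePart	1	-1418038.152084	2837614.101717
AA	19449	GenePart	78	-1413039.660496	2829260.485363
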