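# Prophage regions of Lactococcus lactis subsp. lactis Il1403 (NC_002662):
# manually curated reference coordinates and the predictions of four
# detection tools on the same genome. Coordinates are 1-based inclusive.
# A tool absent for a reference region means the region was missed; rows
# with region "FP" are predictions overlapping no curated prophage.
tool	region	start	end
reference	1	35516	49727
reference	2	447236	483244
reference	3	502723	513742
reference	4	1036642	1071558
reference	5	1414112	1456949
reference	6	2013685	2025635
phaster	1	28461	56371
phaster	2	443651	484066
phaster	3	502338	520485
phaster	4	1033815	1079175
phaster	5	1414112	1457046
phaster	6	1997701	2028023
prophinder	1	35516	49727
prophinder	2	451007	483244
prophinder	3	502723	511542
prophinder	4	1036642	1071558
prophinder	5	1439215	1446438
prophinder	6	2011426	2025635
phispy	1	28818	56368
phispy	2	447083	484064
phispy	4	1036482	1113152
phispy	5	1415361	1457456
phispy	FP	633126	658623
phageweb	1	35516	72698
phageweb	2	447236	483552
phageweb	3	502723	517314
phageweb	4	1036642	1159446
phageweb	5	1415811	1456949
phageweb	6	2013685	2024681
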