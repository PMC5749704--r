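category	total	genic	intergenic
PHR	165885	38276	127609
OTV	26105	4182	21923
MHR	48204	6233	41971
NMH	9730	361	9369
CRBT	16732	2869	13863
Other	13570	2359	11211
HomRO_gt_0.3	148423	29807	118616
HomFLD_gt_10	100138	21873	78265
Diploidized	92419	19158	73261
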