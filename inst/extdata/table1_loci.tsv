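# Published per-locus TSD accounting for three Vietnamese native pigs
# (VnP1-VnP3): detected TSD position/sequence, per-sample status and
# TSD completeness section. Coordinates 1-based (Sscrofa11.1).
chrom	pos	tsd_seq	VnP1	VnP2	VnP3	tsd_section
SSC1	38667241	CTAT	LTR	LTR	LTR	both
SSC1	256173876	CCCC	PERV-B	PERV-B	LTR	both
SSC1	259647577	AATC	LTR	LTR	LTR	both
SSC2	3400723	AGAAC	PERV-B	LTR	LTR	both
SSC4	77324504	CCCC	LTR	LTR	LTR	both
SSC4	78524842	ATTAC	LTR	LTR	LTR	both
SSC4	121221912	GGGG	LTR	LTR	non-LTR	both
SSC6	73460691	GTAT	LTR	LTR	LTR	both
SSC8	137488280	CTAT	LTR	LTR	LTR	both
SSC9	61533579	GGTG	LTR	LTR	non-LTR	both
SSC9	76895449	GAAC	PERV-B	PERV-B	PERV-B	both
SSC9	135717008	AAGAG	LTR	LTR	LTR	both
SSC12	60076460	CTGCT	PERV-B	PERV-B	PERV-B	both
SSC13	57502585	TAAA	LTR	LTR	LTR	both
SSC13	60210737	GTAG	LTR	LTR	non-LTR	both
SSC13	73434304	TTAT	LTR	LTR	non-LTR	both
SSC14	4896607	AGGGT	LTR	LTR	non-LTR	both
SSC14	27599572	ATGC	PERV-B	PERV-B	LTR	both
SSCX	70665683	ATAT	PERV-B	PERV-B	PERV-B	both
SSCX	75151968	CCAG	PERV-B	PERV-B	PERV-B	both
SSCX	119479008	AATT	LTR	LTR	non-LTR	both
SSC8	51601922	ATGA	PERV-C	PERV-C	PERV-C	single
SSC8	137628915	ATGAC	non-LTR	non-LTR	LTR	single
SSC13	107045657	ATTC	PERV-A	non-LTR	non-LTR	single
SSC14	8846347	GAGG	LTR	LTR	non-LTR	single
SSC18	4030456	ATGT	non-LTR	non-LTR	non-LTR	single
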