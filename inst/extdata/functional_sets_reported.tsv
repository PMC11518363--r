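category	set_name	size_G	es	peak_rank	nes	p_nominal	fdr_q	leading_members	members
function	Apoptosis	3	-0.25	NA	NA	0.05	NA	NA	hsa-mir-182,hsa-mir-34a,hsa-mir-210
function	AKT Pathway	8	0.36	NA	NA	0.05	NA	NA	hsa-mir-195,hsa-mir-29c,hsa-mir-20a,hsa-mir-182,hsa-mir-15b,hsa-mir-34a,hsa-let-7g,hsa-mir-210
function	Cell proliferation	4	0.46	NA	NA	0.05	NA	NA	hsa-mir-214,hsa-mir-20a,hsa-mir-205,hsa-mir-331
function	DNA Repair	3	0.48	NA	NA	0.03	NA	NA	hsa-let-7d,hsa-mir-9,hsa-mir-15b
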