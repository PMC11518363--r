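category	set_name	size_G	es	peak_rank	nes	p_nominal	fdr_q	leading_members	members
family	miR-506 Family	2	-0.89	NA	NA	0.05	NA	NA	hsa-mir-512,hsa-mir-509
function	Coregulate MTOR	4	-0.74	NA	NA	0.05	NA	NA	hsa-mir-99a,hsa-mir-100,hsa-mir-182,hsa-mir-199b
regulator	Regulated by TWIST1	3	0.78	NA	NA	0.05	NA	NA	hsa-mir-214,hsa-mir-200b,hsa-mir-205
target	Regulate FGA, FGB, FGG	2	0.91	NA	NA	0.03	NA	NA	hsa-mir-409,hsa-mir-29c
target	Regulate MUC17	2	0.85	NA	NA	0.05	NA	NA	hsa-mir-30c,hsa-mir-20a
target	Regulate APP	2	0.85	NA	NA	0.05	NA	NA	hsa-let-7d,hsa-mir-20a
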