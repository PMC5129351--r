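model	split	accuracy	sensitivity	specificity	youden
gep	train	0.914	0.947	0.905	0.852
gep	test	0.829	0.667	0.885	0.552
mlp	train	0.838	0.844	0.813	0.657
mlp	test	0.743	0.793	0.500	0.293
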