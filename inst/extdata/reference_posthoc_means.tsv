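variable	group	mean
reaction_cnt	1	2.0333
reaction_cnt	2	3.4981
reaction_cnt	3	2.5624
reaction_cnt	4	3.9974
suspect_drug_cnt	1	1.3881
suspect_drug_cnt	2	2.9993
suspect_drug_cnt	3	1.3108
suspect_drug_cnt	4	2.6526
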