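metric	value
polypharmacy_cases_hp	3447
polypharmacy_cases_nonhp	793
polypharmacy_cases_total	4240
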