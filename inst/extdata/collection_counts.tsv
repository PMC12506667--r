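location	year	season	n_sequenced	n_after_filtering
FL	2019	none	25	24
VA-CM	2017	early	20	17
VA-CM	2017	late	20	19
VA-CM	2018	early	20	20
VA-CM	2018	late	20	19
VA-CM	2019	mid	20	20
VA-CM	2019	late	20	14
VA-CM	2020	early	20	18
VA-HPO	2019	mid	20	19
VA-HPO	2020	early	30	29
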