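chrM	65	71	repeat_66_71
chrM	302	311	repeat_303_311
chrM	513	523	repeat_514_523
chrM	12417	12425	repeat_12418_12425
chrM	16183	16193	repeat_16184_16193
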