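participant_id,analyzable_nights,total_nights
1003,12,18
1004,31,31
1012,47,49
1013,34,36
1041,39,47
1048,21,42
1054,44,45
1057,27,27
1061,21,27
1063,33,33
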