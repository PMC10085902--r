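case_id,sample_kind,size,count,flags
case_1,lung,1,3426,
case_2,lung,1,410,
case_3,lung,1,11928,
case_4,lung,1,4521,advanced decomposition
case_5,lung,1,2567,drowning medium contained plenty of debris
case_1,medium,1,315,
case_2,medium,1,175,
case_3,medium,1,3336,
case_4,medium,1,675,
case_5,medium,1,24148,
case_1,liver,1,3,
case_1,kidney,1,14,
case_2,liver,1,0,
case_2,kidney,1,6,
case_3,liver,1,0,
case_3,kidney,1,11,
case_4,liver,1,2,
case_4,kidney,1,9,
case_5,liver,1,1,
case_5,kidney,1,17,
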