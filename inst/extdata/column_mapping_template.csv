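from,to
meta_analysis,phenomenon_id
study_id,study_label
effect_size,estimate
se,standard_error
reverse_coded,direction_flip
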