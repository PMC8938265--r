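subject_id,event_day
T3,10
T3,30
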