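study_id,n_patients,n_events
S1,204,30
S2,220,20
S3,499,14
S4,60,10
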