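design,sex,n_observations
subjective,male,211
subjective,female,107
systematic,male,17
systematic,female,12
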