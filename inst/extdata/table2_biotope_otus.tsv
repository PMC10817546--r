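biotope	otus_its1	otus_its2
subalpine_meadow	171	131
forest	117	60
river_valley	296	221
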