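name,sequence,modifications,charge,target_mz
pep-GG,GG,,1,133.06076
pep-amid,AGK,amidation:-0.98402,1,
pep-long,GASPVKDL,,1,
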