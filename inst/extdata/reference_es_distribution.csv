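group,improbable,possible,probable
Control,37,28,1
MCI-Stable,29,25,20
MCI-AD,3,16,51
ADD,9,35,124
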