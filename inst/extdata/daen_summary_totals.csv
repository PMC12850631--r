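drug,total
pregabalin,2016
gabapentin,426
duloxetine,1008
amitriptyline,573
all drugs,460528
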