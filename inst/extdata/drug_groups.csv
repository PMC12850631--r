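name,ingredients,trade_names
pregabalin,pregabalin,lyrica
gabapentin,gabapentin,neurontin
duloxetine,duloxetine,cymbalta
amitriptyline,amitriptyline,endep;elavil
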