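drug,query_name,n
pregabalin,drug abuse and dependence,418
pregabalin,drug withdrawal,44
pregabalin,suicide and self-injury,208
pregabalin,psychosis and psychotic disorders,187
gabapentin,drug abuse and dependence,35
gabapentin,drug withdrawal,7
gabapentin,suicide and self-injury,26
gabapentin,psychosis and psychotic disorders,38
duloxetine,drug abuse and dependence,126
duloxetine,drug withdrawal,76
duloxetine,suicide and self-injury,124
duloxetine,psychosis and psychotic disorders,61
amitriptyline,drug abuse and dependence,167
amitriptyline,drug withdrawal,7
amitriptyline,suicide and self-injury,45
amitriptyline,psychosis and psychotic disorders,53
all drugs,drug abuse and dependence,9116
all drugs,drug withdrawal,1553
all drugs,suicide and self-injury,4423
all drugs,psychosis and psychotic disorders,8121
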