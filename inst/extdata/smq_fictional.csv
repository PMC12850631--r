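query_name,term,scope
drug abuse and dependence,drug dependence,narrow
drug abuse and dependence,drug abuse,narrow
drug abuse and dependence,substance use disorder,narrow
drug abuse and dependence,drug tolerance,broad_additional
drug abuse and dependence,euphoric mood,broad_additional
drug withdrawal,withdrawal syndrome,narrow
drug withdrawal,drug withdrawal syndrome,narrow
drug withdrawal,rebound pain,broad_additional
suicide and self-injury,suicidal ideation,narrow
suicide and self-injury,suicide attempt,narrow
suicide and self-injury,intentional self-injury,narrow
psychosis and psychotic disorders,hallucination,narrow
psychosis and psychotic disorders,psychotic disorder,narrow
psychosis and psychotic disorders,delusion,narrow
psychosis and psychotic disorders,paranoia,broad_additional
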