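stratum,exposed_cases,exposed_noncases,unexposed_cases,unexposed_noncases
men,100,400,400,100
women,200,300,300,200
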