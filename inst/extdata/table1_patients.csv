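"subject","gender","age","mmse","global_uptake","pet_braak"
"S1","M",54,26,0.26,"IV/V"
"S2","M",69,25,0.22,"III/IV"
"S3","M",74,24,0.13,"III/IV"
"S4","M",61,22,0.26,"III/IV"
"S5","M",77,29,0.19,"I/II"
"S6","F",64,20,0.3,"III/IV"
"S7","F",82,25,0.12,"I/II"
"S8","M",82,24,0.17,"III/IV"
"S9","F",73,22,0.23,"IV/V"
"S10","M",56,24,0.31,"III/IV"
"S11","M",64,25,0.23,"III/IV"
"S12","M",78,23,0.16,"III/IV"
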