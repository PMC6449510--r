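term,estimate
intercept,0.319
temp_minus_20,-0.025
glucose,0.172
latitude,-0.006
longitude,-0.001
map,0.0002
ph,0.032
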