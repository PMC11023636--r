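condition,parameter,fold
knockout,mu_r,1.3
knockout,mu_nr,1.4
knockout,mu_s,1.2
knockout,d,1.25
gain_of_function,mu_r,1.4
gain_of_function,mu_nr,0.75
gain_of_function,mu_s,1.3
gain_of_function,d,1.0
agonist,mu_r,0.8
agonist,mu_nr,0.7
agonist,mu_s,1.35
agonist,d,1.0
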