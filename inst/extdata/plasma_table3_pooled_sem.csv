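response,pooled_sem
Asp,4.2
Ser,9.87
Gln,21.6
Ala,14.7
Met,6.66
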