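dimension,sex,baseline_coefficient,enriched_coefficient
northness,male,0.0078,0.0005
northness,female,0.0057,0.0005
westness,male,0.0067,0.0013
westness,female,0.0042,0.0007
centrality,male,0.0105,0.0009
centrality,female,0.0073,0.0006
contiguity,male,0.7224,0.0404
contiguity,female,0.7650,0.0894
proximity,male,1.9100,-0.0562
proximity,female,1.9156,0.0749
urbanity,male,22.3832,2.6274
urbanity,female,5.3561,1.0377
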