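name	chrom	start	end
IC1	chr11	1998745	2003509
IC2	chr11	2697587	2700983
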