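probe_id	coefficient
cg05809947	-0.10
cg12219311	-0.08
cg26466505	-0.07
cg20691428	-0.07
cg20869305	0.09
cg22174844	0.16
cg26225829	-0.13
cg04947065	0.06
cg16575694	-0.09
cg16559598	0.07
cg08729004	-0.09
cg13635578	-0.03
cg13744452	-0.04
cg04817034	-0.02
cg07130508	0.02
cg00226265	-0.04
cg13749939	0.06
cg25817165	0.05
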