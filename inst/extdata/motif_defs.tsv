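name	start	end
Mis12C-binding	1	45
R-rich	101	135
DH	201	245
AT1	401	415
AT2	501	515
NLS	701	720
Cenp-C motif	1081	1125
Cupin	1280	1360
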