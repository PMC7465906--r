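gene	position	posterior	branch
CALR	83	0.971	Vertebrata
CALR	155	0.971	Vertebrata
CALR	177	0.990	Vertebrata
CALR	267	0.995	Vertebrata
CALR	307	0.994	Vertebrata
CALR	336	0.991	Vertebrata
CALR	360	0.999	Vertebrata
CTNNB1	121	0.999	Vertebrata
CTNNB1	206	0.993	Vertebrata
CTNNB1	250	0.998	Vertebrata
CTNNB1	287	0.991	Vertebrata
CTNNB1	411	0.998	Vertebrata
CTNNB1	433	0.993	Vertebrata
CTNNB1	525	0.997	Vertebrata
CTNNB1	552	0.998	Vertebrata
CTNNB1	556	0.916	Vertebrata
VHL	127	0.957	Vertebrata
VHL	132	0.942	Vertebrata
VHL	141	0.923	Vertebrata
VHL	171	0.947	Vertebrata
VHL	183	0.963	Vertebrata
VHL	185	0.920	Vertebrata
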