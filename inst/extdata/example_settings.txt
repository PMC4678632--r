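MICROSCOPE	TCS SP2 (synthetic example in the epidepth settings dialect)
SOFTWARE_VERSION	2.61
OBJECTIVE_MAGNIFICATION	63
NUMERICAL_APERTURE	1.32
IMMERSION	oil
PIXEL_SIZE_NM	160
FRAME_AVERAGING	4
Z_INTERVAL_UM	10
GAIN	1
OFFSET	0
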