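nominal_wavelength_nm,intensity_min_uW,intensity_max_uW,beam_angle_deg,band
466,15,30,38,visible
585,15,30,38,visible
626,15,30,38,visible
810,15,30,38,near_ir
850,15,30,38,near_ir
950,15,30,38,near_ir
3400,15,30,38,far_ir
3600,15,30,38,far_ir
3800,15,30,38,far_ir
3900,15,30,38,far_ir
4100,15,30,38,far_ir
4300,15,30,38,far_ir
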