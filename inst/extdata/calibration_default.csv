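cell_line,assay,regime_id,wavelength_nm,true_viability_pct,source
HEM,LDH,1,466,100,null_control
HEM,LDH,1,585,100,null_control
HEM,LDH,1,626,100,null_control
HEM,LDH,1,810,100,null_control
HEM,LDH,1,850,100,null_control
HEM,LDH,1,950,100,null_control
HEM,LDH,1,3400,100,null_control
HEM,LDH,1,3600,100,null_control
HEM,LDH,1,3800,100,null_control
HEM,LDH,1,3900,100,null_control
HEM,LDH,1,4100,100,null_control
HEM,LDH,1,4300,100,null_control
HEM,LDH,2,466,100,null_control
HEM,LDH,2,585,100,null_control
HEM,LDH,2,626,100,null_control
HEM,LDH,2,810,100,null_control
HEM,LDH,2,850,100,null_control
HEM,LDH,2,950,100,null_control
HEM,LDH,2,3400,100,null_control
HEM,LDH,2,3600,100,null_control
HEM,LDH,2,3800,100,null_control
HEM,LDH,2,3900,100,null_control
HEM,LDH,2,4100,100,null_control
HEM,LDH,2,4300,100,null_control
HEM,LDH,3,466,100,null_control
HEM,LDH,3,585,100,null_control
HEM,LDH,3,626,100,null_control
HEM,LDH,3,810,100,null_control
HEM,LDH,3,850,100,null_control
HEM,LDH,3,950,100,null_control
HEM,LDH,3,3400,100,null_control
HEM,LDH,3,3600,100,null_control
HEM,LDH,3,3800,100,null_control
HEM,LDH,3,3900,100,null_control
HEM,LDH,3,4100,100,null_control
HEM,LDH,3,4300,100,null_control
HEM,PrestoBlue,1,466,100,null_control
HEM,PrestoBlue,1,585,100,null_control
HEM,PrestoBlue,1,626,100,null_control
HEM,PrestoBlue,1,810,100,null_control
HEM,PrestoBlue,1,850,100,null_control
HEM,PrestoBlue,1,950,100,null_control
HEM,PrestoBlue,1,3400,100,null_control
HEM,PrestoBlue,1,3600,100,null_control
HEM,PrestoBlue,1,3800,100,null_control
HEM,PrestoBlue,1,3900,100,null_control
HEM,PrestoBlue,1,4100,100,null_control
HEM,PrestoBlue,1,4300,100,null_control
HEM,PrestoBlue,2,466,100,null_control
HEM,PrestoBlue,2,585,100,null_control
HEM,PrestoBlue,2,626,100,null_control
HEM,PrestoBlue,2,810,100,null_control
HEM,PrestoBlue,2,850,100,null_control
HEM,PrestoBlue,2,950,100,null_control
HEM,PrestoBlue,2,3400,100,null_control
HEM,PrestoBlue,2,3600,100,null_control
HEM,PrestoBlue,2,3800,100,null_control
HEM,PrestoBlue,2,3900,100,null_control
HEM,PrestoBlue,2,4100,100,null_control
HEM,PrestoBlue,2,4300,100,null_control
HEM,PrestoBlue,3,466,100,null_control
HEM,PrestoBlue,3,585,100,null_control
HEM,PrestoBlue,3,626,100,null_control
HEM,PrestoBlue,3,810,100,null_control
HEM,PrestoBlue,3,850,100,null_control
HEM,PrestoBlue,3,950,100,null_control
HEM,PrestoBlue,3,3400,100,null_control
HEM,PrestoBlue,3,3600,100,null_control
HEM,PrestoBlue,3,3800,100,null_control
HEM,PrestoBlue,3,3900,100,null_control
HEM,PrestoBlue,3,4100,100,null_control
HEM,PrestoBlue,3,4300,100,null_control
MCF7,LDH,1,466,98,illustrative_visible
MCF7,LDH,1,585,98,illustrative_visible
MCF7,LDH,1,626,98,illustrative_visible
MCF7,LDH,1,810,95,illustrative_near_ir
MCF7,LDH,1,850,95,illustrative_near_ir
MCF7,LDH,1,950,95,illustrative_near_ir
MCF7,LDH,1,3400,92,results_ldh
MCF7,LDH,1,3600,86,results_ldh
MCF7,LDH,1,3800,91,results_ldh
MCF7,LDH,1,3900,90,results_ldh
MCF7,LDH,1,4100,90,results_ldh
MCF7,LDH,1,4300,91,results_ldh
MCF7,LDH,2,466,97,illustrative_visible
MCF7,LDH,2,585,97,illustrative_visible
MCF7,LDH,2,626,97,illustrative_visible
MCF7,LDH,2,810,93,illustrative_near_ir
MCF7,LDH,2,850,93,illustrative_near_ir
MCF7,LDH,2,950,93,illustrative_near_ir
MCF7,LDH,2,3400,82,results_ldh
MCF7,LDH,2,3600,76,results_ldh
MCF7,LDH,2,3800,81,results_ldh
MCF7,LDH,2,3900,80,results_ldh
MCF7,LDH,2,4100,80,results_ldh
MCF7,LDH,2,4300,81,results_ldh
MCF7,LDH,3,466,96,illustrative_visible
MCF7,LDH,3,585,96,illustrative_visible
MCF7,LDH,3,626,96,illustrative_visible
MCF7,LDH,3,810,91,illustrative_near_ir
MCF7,LDH,3,850,91,illustrative_near_ir
MCF7,LDH,3,950,91,illustrative_near_ir
MCF7,LDH,3,3400,72,results_ldh
MCF7,LDH,3,3600,66,results_ldh
MCF7,LDH,3,3800,71,results_ldh
MCF7,LDH,3,3900,70,results_ldh
MCF7,LDH,3,4100,70,results_ldh
MCF7,LDH,3,4300,71,results_ldh
MCF7,PrestoBlue,1,466,98,illustrative_visible
MCF7,PrestoBlue,1,585,98,illustrative_visible
MCF7,PrestoBlue,1,626,98,illustrative_visible
MCF7,PrestoBlue,1,810,95,illustrative_near_ir
MCF7,PrestoBlue,1,850,95,illustrative_near_ir
MCF7,PrestoBlue,1,950,95,illustrative_near_ir
MCF7,PrestoBlue,1,3400,87,results_prestoblue
MCF7,PrestoBlue,1,3600,75,results_prestoblue
MCF7,PrestoBlue,1,3800,86,results_prestoblue
MCF7,PrestoBlue,1,3900,85,results_prestoblue
MCF7,PrestoBlue,1,4100,84,results_prestoblue
MCF7,PrestoBlue,1,4300,86,results_prestoblue
MCF7,PrestoBlue,2,466,97,illustrative_visible
MCF7,PrestoBlue,2,585,97,illustrative_visible
MCF7,PrestoBlue,2,626,97,illustrative_visible
MCF7,PrestoBlue,2,810,93,illustrative_near_ir
MCF7,PrestoBlue,2,850,93,illustrative_near_ir
MCF7,PrestoBlue,2,950,93,illustrative_near_ir
MCF7,PrestoBlue,2,3400,84,results_prestoblue
MCF7,PrestoBlue,2,3600,72,results_prestoblue
MCF7,PrestoBlue,2,3800,83,results_prestoblue
MCF7,PrestoBlue,2,3900,82,results_prestoblue
MCF7,PrestoBlue,2,4100,81,results_prestoblue
MCF7,PrestoBlue,2,4300,83,results_prestoblue
MCF7,PrestoBlue,3,466,96,illustrative_visible
MCF7,PrestoBlue,3,585,96,illustrative_visible
MCF7,PrestoBlue,3,626,96,illustrative_visible
MCF7,PrestoBlue,3,810,91,illustrative_near_ir
MCF7,PrestoBlue,3,850,91,illustrative_near_ir
MCF7,PrestoBlue,3,950,91,illustrative_near_ir
MCF7,PrestoBlue,3,3400,76,results_prestoblue
MCF7,PrestoBlue,3,3600,64,results_prestoblue
MCF7,PrestoBlue,3,3800,75,results_prestoblue
MCF7,PrestoBlue,3,3900,74,results_prestoblue
MCF7,PrestoBlue,3,4100,73,results_prestoblue
MCF7,PrestoBlue,3,4300,75,results_prestoblue
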