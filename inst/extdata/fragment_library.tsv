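id	formula	instrument_mode	retained_positions	n_derivatization_carbons	note
3PGA_459	C14H36O7PSi4+	both	1,2,3	11	3PGA (4TMS): EI [M]+ - CH3 radical; APCI [M+H]+ - CH4; all three metabolite carbons
3PGA_357	C11H30O5PSi3+	both	2,3	9	3PGA (4TMS): EI [M]+ - TMSCOO radical; APCI [M+H]+ - TMSCOOH; cleavage between 1-C and 2-C
3PGA_299	C8H24O4PSi3+	EI	-	8	silylated-phosphate qualifier fragment, receives no 13C label; quantification qualifier only
3PGA_315	C9H28O4PSi3+	EI	-	9	silylated-phosphate qualifier fragment, receives no 13C label; quantification qualifier only
G6P_706	C24H61NO9PSi6+	APCI	1,2,3,4,5,6	18	G6P (1MEOX)(6TMS) [M+H-CH4]+, exact m/z 706.2694; reference for labeling-adjustment
GLC_554	C21H52NO6Si5+	APCI	1,2,3,4,5,6	15	glucose (1MEOX)(5TMS) [M+H-CH4]+; tracer-substrate validation fragment
SORB_599	C23H59O6Si6+	APCI	1,2,3,4,5,6	17	sorbitol (6TMS) [M+H-CH4]+; 13C6-sorbitol internal standard channel
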