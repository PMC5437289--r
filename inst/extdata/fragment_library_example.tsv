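metabolite	fragment_formula	n_carbons	base_mz
proline	C16H34NO2Si2	5	258
glutamate	C19H42NO4Si3	5	432
lactate	C12H27O3Si2	3	261
alanine	C14H32NO2Si2	3	260
serine	C20H46NO3Si3	3	390
citrate	C26H55O7Si4	6	591
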