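"name","kind","subset","partition","channel","numerator","denominator"
"MFI_M_NKbright_M","mfi","NKbright","M","CD16-MEM154","",""
"MFI_L_NKbright_M","mfi","NKbright","M","CD16-LNK16","",""
"F_NKbright_M","freq_nk","NKbright","M","","",""
"Ft_NKbright_M","freq_total","NKbright","M","","",""
"MFI_M_NKdim_M","mfi","NKdim","M","CD16-MEM154","",""
"MFI_L_NKdim_M","mfi","NKdim","M","CD16-LNK16","",""
"F_NKdim_M","freq_nk","NKdim","M","","",""
"Ft_NKdim_M","freq_total","NKdim","M","","",""
"MFI_M_NKdimneg_M","mfi","NKdimneg","M","CD16-MEM154","",""
"MFI_L_NKdimneg_M","mfi","NKdimneg","M","CD16-LNK16","",""
"F_NKdimneg_M","freq_nk","NKdimneg","M","","",""
"Ft_NKdimneg_M","freq_total","NKdimneg","M","","",""
"MFI_M_NKbright_L","mfi","NKbright","L","CD16-MEM154","",""
"MFI_L_NKbright_L","mfi","NKbright","L","CD16-LNK16","",""
"F_NKbright_L","freq_nk","NKbright","L","","",""
"Ft_NKbright_L","freq_total","NKbright","L","","",""
"MFI_M_NKdim_L","mfi","NKdim","L","CD16-MEM154","",""
"MFI_L_NKdim_L","mfi","NKdim","L","CD16-LNK16","",""
"F_NKdim_L","freq_nk","NKdim","L","","",""
"Ft_NKdim_L","freq_total","NKdim","L","","",""
"MFI_M_NKdimneg_L","mfi","NKdimneg","L","CD16-MEM154","",""
"MFI_L_NKdimneg_L","mfi","NKdimneg","L","CD16-LNK16","",""
"F_NKdimneg_L","freq_nk","NKdimneg","L","","",""
"Ft_NKdimneg_L","freq_total","NKdimneg","L","","",""
"rMFI_NKbrightML","ratio_mfi","NKbright","","","MFI_M_NKbright_M","MFI_L_NKbright_L"
"rF_NKbrightML","ratio_freq","NKbright","","","F_NKbright_M","F_NKbright_L"
"rMFI_NKdimML","ratio_mfi","NKdim","","","MFI_M_NKdim_M","MFI_L_NKdim_L"
"rF_NKdimML","ratio_freq","NKdim","","","F_NKdim_M","F_NKdim_L"
"rMFI_NKdimnegML","ratio_mfi","NKdimneg","","","MFI_M_NKdimneg_M","MFI_L_NKdimneg_L"
"rF_NKdimnegML","ratio_freq","NKdimneg","","","F_NKdimneg_M","F_NKdimneg_L"
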