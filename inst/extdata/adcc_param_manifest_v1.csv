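"name","population","kind","marker"
"tumour_freq","tumour","freq",""
"tumour_viable_pct","tumour","viability","viable"
"tumour_dead_pct","tumour","viability","dead"
"tumour_dapi_only_pct","tumour","viability","dapi_only"
"tumour_annexin_only_pct","tumour","viability","annexin_only"
"tumour_PDL1_pct","tumour","marker_pct","PDL1"
"tumour_PDL1_mfi","tumour","marker_mfi","PDL1"
"tumour_CD40_pct","tumour","marker_pct","CD40"
"tumour_CD40_mfi","tumour","marker_mfi","CD40"
"tumour_EpCAM_mfi","tumour","marker_mfi","EpCAM"
"tumour_DAPI_mfi","tumour","marker_mfi","DAPI"
"tumour_AnnexinV_mfi","tumour","marker_mfi","AnnexinV"
"NK_freq","NK","freq",""
"NK_CD16_pct","NK","marker_pct","CD16"
"NK_CD16_mfi","NK","marker_mfi","CD16"
"NK_CD56_mfi","NK","marker_mfi","CD56"
"NK_CD107a_pct","NK","marker_pct","CD107a"
"NK_CD107a_mfi","NK","marker_mfi","CD107a"
"NK_CD137_pct","NK","marker_pct","CD137"
"NK_CD137_mfi","NK","marker_mfi","CD137"
"NK_PD1_pct","NK","marker_pct","PD1"
"NK_PD1_mfi","NK","marker_mfi","PD1"
"NK_NKG2A_pct","NK","marker_pct","NKG2A"
"NK_NKG2A_mfi","NK","marker_mfi","NKG2A"
"NK_NKG2D_pct","NK","marker_pct","NKG2D"
"NK_NKG2D_mfi","NK","marker_mfi","NKG2D"
"NK_CD62L_pct","NK","marker_pct","CD62L"
"NK_CD62L_mfi","NK","marker_mfi","CD62L"
"NKdim_freq","NK_dim","freq",""
"NKdim_CD16_mfi","NK_dim","marker_mfi","CD16"
"NKdim_CD107a_pct","NKdim","marker_pct","CD107a"
"NKdim_CD107a_mfi","NKdim","marker_mfi","CD107a"
"NKdim_CD137_pct","NKdim","marker_pct","CD137"
"NKdim_CD137_mfi","NKdim","marker_mfi","CD137"
"NKdim_PD1_pct","NKdim","marker_pct","PD1"
"NKdim_PD1_mfi","NKdim","marker_mfi","PD1"
"NKdim_NKG2A_pct","NKdim","marker_pct","NKG2A"
"NKdim_NKG2A_mfi","NKdim","marker_mfi","NKG2A"
"NKdim_NKG2D_pct","NKdim","marker_pct","NKG2D"
"NKdim_NKG2D_mfi","NKdim","marker_mfi","NKG2D"
"NKdim_CD62L_pct","NKdim","marker_pct","CD62L"
"NKdim_CD62L_mfi","NKdim","marker_mfi","CD62L"
"NKbright_freq","NK_bright","freq",""
"NKbright_CD107a_pct","NKbright","marker_pct","CD107a"
"NKbright_CD107a_mfi","NKbright","marker_mfi","CD107a"
"NKbright_CD137_pct","NKbright","marker_pct","CD137"
"NKbright_CD137_mfi","NKbright","marker_mfi","CD137"
"NKbright_PD1_pct","NKbright","marker_pct","PD1"
"NKbright_PD1_mfi","NKbright","marker_mfi","PD1"
"NKbright_NKG2A_pct","NKbright","marker_pct","NKG2A"
"NKbright_NKG2A_mfi","NKbright","marker_mfi","NKG2A"
"NKbright_NKG2D_pct","NKbright","marker_pct","NKG2D"
"NKbright_NKG2D_mfi","NKbright","marker_mfi","NKG2D"
"NKbright_CD62L_pct","NKbright","marker_pct","CD62L"
"NKbright_CD62L_mfi","NKbright","marker_mfi","CD62L"
"T_freq","T","freq",""
"T_CD107a_pct","T","marker_pct","CD107a"
"T_CD107a_mfi","T","marker_mfi","CD107a"
"T_CD137_pct","T","marker_pct","CD137"
"T_CD137_mfi","T","marker_mfi","CD137"
"T_PD1_pct","T","marker_pct","PD1"
"T_PD1_mfi","T","marker_mfi","PD1"
"T_NKG2A_pct","T","marker_pct","NKG2A"
"T_NKG2A_mfi","T","marker_mfi","NKG2A"
"T_NKG2D_pct","T","marker_pct","NKG2D"
"T_NKG2D_mfi","T","marker_mfi","NKG2D"
"T_CD62L_pct","T","marker_pct","CD62L"
"T_CD62L_mfi","T","marker_mfi","CD62L"
"mono_freq","monocytes","freq",""
"mono_CD40_pct","mono","marker_pct","CD40"
"mono_CD40_mfi","mono","marker_mfi","CD40"
"mono_PDL1_pct","mono","marker_pct","PDL1"
"mono_PDL1_mfi","mono","marker_mfi","PDL1"
"mono_CD62L_pct","mono","marker_pct","CD62L"
"mono_CD62L_mfi","mono","marker_mfi","CD62L"
"mono_PD1_pct","mono","marker_pct","PD1"
"mono_PD1_mfi","mono","marker_mfi","PD1"
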