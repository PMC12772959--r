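id,ligand,receptor
WNT9B_FZD3_LRP5,Wnt9b,Fzd3+Lrp5
WNT5A_FZD3_LRP6,Wnt5a,Fzd3+Lrp6
PDGFB_PDGFRB,Pdgfb,Pdgfrb
GDNF_RET_GFRA1,Gdnf,Ret+Gfra1
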