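case,a_est,a_lo,a_hi,b_est,b_lo,b_hi,ab_est,ab_lo,ab_hi,di_lo,di_hi,type,audit
dI_spans_zero,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-1.6,-1.7,-1.5,-0.5,0.4,additive,FALSE
neg_singles_combined_null,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-0.05,-0.3,0.2,0.2,0.8,neutralizing,FALSE
neg_singles_combined_between,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-1.1,-1.2,-1.0,0.2,0.8,weak_antagonistic,FALSE
neg_singles_combined_small,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-0.3,-0.4,-0.2,0.2,0.8,strong_antagonistic,FALSE
neg_singles_combined_oversum,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-1.8,-1.9,-1.7,0.2,0.8,strong_antagonistic,TRUE
neg_singles_dI_below,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-1.6,-1.7,-1.5,-0.8,-0.2,synergistic,FALSE
opposite_singles_dI_below,0.9,0.8,1.0,-0.7,-0.8,-0.6,-0.1,-0.3,0.1,-0.8,-0.2,synergistic,FALSE
pos_singles_dI_below_null_combined,0.9,0.8,1.0,0.7,0.6,0.8,0.05,-0.2,0.3,-0.8,-0.2,neutralizing,FALSE
pos_singles_dI_above,0.9,0.8,1.0,0.7,0.6,0.8,1.6,1.5,1.7,0.2,0.8,synergistic,FALSE
pos_singles_combined_between,0.9,0.8,1.0,0.7,0.6,0.8,1.1,1.0,1.2,-0.8,-0.2,weak_antagonistic,FALSE
pos_singles_combined_small,0.9,0.8,1.0,0.7,0.6,0.8,0.3,0.2,0.4,-0.8,-0.2,strong_antagonistic,FALSE
opposite_singles_combined_null,0.9,0.8,1.0,-0.4,-0.5,-0.3,-0.05,-0.2,0.1,0.3,0.9,neutralizing,FALSE
opposite_singles_combined_small,0.9,0.8,1.0,-0.4,-0.5,-0.3,-0.2,-0.3,-0.1,0.3,0.9,strong_antagonistic,FALSE
opposite_singles_combined_between,0.9,0.8,1.0,-0.4,-0.5,-0.3,0.45,0.35,0.55,0.3,0.9,weak_antagonistic,FALSE
tie_combined_equals_min_single,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-0.7,-0.8,-0.6,0.2,0.8,weak_antagonistic,FALSE
all_nonsignificant_antagonistic,-0.2,-0.5,0.1,-0.1,-0.4,0.2,-0.05,-0.35,0.25,0.2,0.8,strong_antagonistic,TRUE
dI_touching_zero,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-1.6,-1.7,-1.5,0.0,0.4,additive,FALSE
combined_just_under_sum,-0.9,-1.0,-0.8,-0.7,-0.8,-0.6,-1.55,-1.65,-1.45,0.2,0.8,weak_antagonistic,FALSE
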