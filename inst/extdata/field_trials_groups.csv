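group,submergence_days,submergence_days_sd,cumulative_water_depth,cumulative_water_depth_sd,yield_ct,yield_ct_sd,yield_nk,yield_nk_sd,yield_nkpr,yield_nkpr_sd,yield_nktsp,yield_nktsp_sd,increase_nk,increase_nk_sd,increase_nkpr,increase_nkpr_sd,increase_nktsp,increase_nktsp_sd
Lixisols and Luvisols,29,7,135,71,0.86,0.78,1.63,0.98,3.37,1.17,4.10,1.20,0.77,0.88,2.51,1.46,3.24,1.42
Cambisols,61,23,506,315,1.79,0.64,2.39,1.03,3.74,1.37,4.23,2.81,0.60,0.86,1.95,1.48,2.44,2.51
All sites,43,22,294,279,1.24,0.85,1.93,1.05,3.52,1.23,4.15,1.94,0.70,0.86,2.28,1.45,2.91,1.91
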