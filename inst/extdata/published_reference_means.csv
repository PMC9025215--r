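time_slice,ssp,loss_pct,gain_pct,overall_change_pct,occ_lost_pct
2070,SSP1-2.6,25.09,17.64,-7.45,13.60
2070,SSP5-8.5,38.48,22.90,-15.59,27.65
2090,SSP1-2.6,22.61,17.06,-5.55,12.08
2090,SSP5-8.5,48.87,21.35,-27.51,40.12
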