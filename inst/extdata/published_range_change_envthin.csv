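time_slice,ssp,gcm,loss_pct,gain_pct,overall_change_pct,occ_lost_pct
2070,SSP1-2.6,BC,20.58,17.45,-3.14,8.27
2070,SSP1-2.6,MI,16.40,21.12,4.72,10.54
2070,SSP1-2.6,MR,38.29,14.36,-23.93,22.03
2070,SSP5-8.5,BC,51.42,23.89,-27.54,38.46
2070,SSP5-8.5,MI,20.03,29.36,9.33,13.37
2070,SSP5-8.5,MR,44.00,15.44,-28.55,31.13
2090,SSP1-2.6,BC,20.07,15.03,-5.04,8.99
2090,SSP1-2.6,MI,16.13,22.91,6.78,10.27
2090,SSP1-2.6,MR,31.64,13.25,-18.39,16.98
2090,SSP5-8.5,BC,77.03,25.65,-51.38,73.20
2090,SSP5-8.5,MI,40.51,23.41,-17.09,30.91
2090,SSP5-8.5,MR,29.06,15.00,-14.06,16.26
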