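# Printed per-feature summary (mean, SD, p, percent change) from a published
# ex vivo whole-heart gap-junction-uncoupling study (automated unipolar EGM
# analysis, baseline vs carbenoxolone). Worked-example inputs, not targets.
feature,bl_mean,bl_sd,cbx_mean,cbx_sd,p_printed,pct_change_printed
rs_interval,182.01,1093.43,149.96,1061.53,0.42,-17.61
qr_interval,68.59,154.71,63.21,164.99,0.34,-7.84
qs_interval,250.60,1151.87,213.17,1159.46,0.37,-14.94
egm_duration,292.98,1155.80,265.20,1163.59,0.51,-9.48
q_point,0.81,0.96,0.92,1.05,0.002,13.86
r_point,3.13,7.92,2.55,2.12,0.03,-18.60
s_point,-3.40,3.06,-4.74,2.66,<0.0001,-39.40
endpoint_amplitude,-0.24,2.02,-0.50,2.14,0.0005,-106.85
rs_gradient,-0.31,1.01,-0.36,0.33,0.11,-17.79
qr_gradient,0.06,0.24,0.06,0.10,0.91,-1.49
s_endpoint_gradient,0.17,0.29,0.26,1.40,<0.0001,54.93
fractionation_index,29.27,89.76,83.52,327.44,<0.0001,185.30
r_width,159.59,613.57,138.19,635.67,0.34,-13.41
s_width,133.39,553.10,127.01,127.01,0.75,-4.78
rs_ratio,-1.35,1.81,-0.83,1.06,<0.0001,38.58
rs_width_ratio,1.95,4.28,1.97,8.06,0.91,1.04
rs_width_over_duration,0.50,0.21,0.48,0.23,0.005,-4.30
dvdt_max,2.17,7.83,1.72,2.01,0.08,-20.94
amplitude,6.53,9.39,7.28,3.21,0.02,11.58
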