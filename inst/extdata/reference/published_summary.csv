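metric,treated,control
pct_wins_death,7.15,4.01
pct_wins_hfe_count,10.59,7.65
pct_wins_hfe_first_time,0.24,0.57
pct_wins_kccq,35.91,27.48
pct_wins_total,53.89,39.71
pct_ties,6.41,6.41
win_ratio_printed,1.36,
n_randomized,265,265
deaths_n,11,22
diuretic_response_adj_mean_d15,-3.33,-1.02
diuretic_response_adj_mean_d30,-3.80,-1.01
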