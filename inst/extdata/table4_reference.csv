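id,cost_cmp,cost_tx,delta_cost,effect_cmp,effect_tx,delta_effect,icer
base_5pct,56560,347377,290816,9.59,11.52,1.94,150006
disc_3.5pct,67363,369647,302284,11.14,13.51,2.37,127278
disc_3pct,71695,378532,306837,11.76,14.31,2.56,120008
undiscounted,109303,455743,346440,17.08,21.36,4.28,80917
base_5pct_ly,56560,347377,290816,14.08,15.12,1.05,278188
undiscounted_ly,109303,455743,346440,25.30,28.63,3.33,104177
undiscounted_double_dis,109303,455743,346440,14.29,19.86,5.56,62254
generic,56560,273741,217180,9.59,11.52,1.94,112023
generic_1pct,94062,320265,226203,14.93,18.48,3.55,63668
generic_tx_minus20k,56560,231843,175283,9.59,11.52,1.94,90412
increased_iit_drc_costs,66426,352527,286100,9.59,11.52,1.94,147573
increased_costs_undisc_double_dis,129361,468444,339083,14.29,19.86,5.56,60932
le10_5pct,60863,349993,289130,9.93,11.73,1.80,160394
le10_3pct,78527,382868,304341,12.30,14.66,2.36,128877
le10_undisc_ly,123916,465610,341694,27.20,29.94,2.74,124804
le14_5pct,51693,344471,292778,9.22,11.31,2.09,140095
le14_3pct,64301,373931,309630,11.20,13.96,2.77,111867
le14_undisc_ly,94621,446014,351393,23.43,27.36,3.93,89402
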