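temperature_C,psi_MPa,tt_sub,tt_supra,theta_h,theta_htt,gr_tt,gr_ht
15,0,187.2,1123.2,56.16,280.8,0.027562,0.027562
15,-0.3,129.6,777.6,38.58,155.52,0.039195,0.031608
15,-0.6,97.6,585.6,28.68,87.84,0.052403,0.03213
15,-0.9,79.2,475.2,22.86,47.52,0.066032,0.027562
15,-1.2,89.6,537.6,25.68,26.88,0.058544,0.012311
20,0,272,680,40.8,408,0.03736,0.03736
20,-0.3,219.2,548,32.88,263.04,0.046151,0.036921
20,-0.6,192,480,28.8,172.8,0.054653,0.032792
20,-0.9,179.2,448,26.88,107.52,0.060524,0.02421
20,-1.2,137.6,344,20.64,41.28,0.073142,0.014628
25,0,631.2,841.6,63.12,946.8,0.023844,0.023844
25,-0.3,652.8,870.4,65.28,783.36,0.023188,0.01855
25,-0.6,520.8,694.4,52.08,468.72,0.02959,0.017754
25,-0.9,391.2,521.6,39.12,234.72,0.038659,0.015464
25,-1.2,381.6,508.8,38.16,114.48,0.039308,0.007862
30,0,995.2,746.4,74.64,1492.8,0.020141,0.020141
30,-0.3,988.8,741.6,74.16,1186.56,0.020331,0.016265
30,-0.6,726.4,544.8,54.48,653.76,0.027898,0.016739
30,-0.9,460.8,345.6,34.56,276.48,0.043489,0.017395
30,-1.2,422.4,316.8,31.68,126.72,0.047947,0.009589
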