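slice,psnr_mvar,psnr_mfix,psnr_jp2k,mse_mvar,mse_mfix,mse_jp2k
1,40.70,19.31,31.00,5.52,761.83,51.59
100,40.25,23.96,31.43,6.13,260.86,46.71
200,41.78,21.43,32.92,4.31,466.91,33.14
300,42.10,23.46,35.47,4.00,292.95,18.44
400,40.46,42.51,39.96,5.83,3.64,6.55
500,40.98,78,41.28,5.18,0.001,4.83
600,54.02,78,40.38,0.25,0.001,5.95
700,43.29,78,42.43,3.04,0.001,3.71
800,54.89,78,44.13,0.21,0.001,2.50
900,57.85,78,42.79,0.10,0.001,3.42
1000,56.29,78,45.01,0.15,0.001,2.05
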