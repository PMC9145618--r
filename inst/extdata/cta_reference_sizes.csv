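method,avg_slice_kb,cr_printed
Original file,512,1:1
Lossless JPEG2000,145.95,3.5:1
Lossless JP3D,142.78,3.6:1
Lossless H.264,170.3,3:1
MVAR,56.44,9:1
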