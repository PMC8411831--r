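# Complex refractive index of evaporated gold films
# P. B. Johnson and R. W. Christy, Phys. Rev. B 6, 4370 (1972), Table 1
# (photon energies 0.64-6.60 eV converted to vacuum wavelength in nm)
wavelength_nm n k
187.855 1.280 1.188
191.629 1.320 1.203
195.251 1.340 1.226
199.331 1.330 1.251
203.253 1.330 1.277
207.331 1.300 1.304
211.939 1.300 1.350
216.377 1.300 1.387
221.400 1.300 1.427
226.249 1.310 1.460
231.314 1.300 1.497
237.063 1.320 1.536
242.631 1.320 1.577
248.964 1.330 1.631
255.112 1.330 1.688
261.570 1.350 1.749
268.946 1.380 1.803
276.134 1.430 1.847
284.367 1.470 1.869
292.416 1.490 1.878
300.932 1.530 1.889
310.737 1.530 1.893
320.373 1.540 1.898
331.509 1.480 1.883
342.498 1.480 1.871
354.241 1.500 1.866
367.906 1.480 1.895
381.490 1.460 1.933
397.385 1.470 1.952
413.281 1.460 1.958
430.501 1.450 1.948
450.852 1.380 1.914
471.423 1.310 1.849
495.937 1.040 1.833
520.942 0.620 2.081
548.603 0.430 2.455
582.085 0.290 2.863
616.837 0.210 3.272
659.490 0.140 3.697
704.456 0.130 4.103
756.001 0.140 4.542
821.087 0.160 5.083
891.973 0.170 5.663
984.002 0.220 6.350
1087.581 0.270 7.150
1215.531 0.350 8.145
1393.081 0.430 9.519
1610.184 0.560 11.210
1937.253 0.920 13.780
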