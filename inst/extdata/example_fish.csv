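fish_id,lake_id,standard_length_mm,wet_mass_g,d13C,d15N
L01_f01,L01,152.13,35.38,-24.06,7.07
L01_f02,L01,156.75,43.39,-25.14,8.05
L01_f03,L01,147.18,29.39,-25.9,7.72
L01_f04,L01,144.31,33.02,-26.13,6.75
L01_f05,L01,169.41,54.82,-24.65,8.44
L01_f06,L01,136.52,31.56,-25.94,7.62
L02_f01,L02,146.36,36.07,-26.52,7.53
L02_f02,L02,138.52,28.15,-25.42,6.87
L02_f03,L02,147.87,28.35,-26.28,7.47
L02_f04,L02,152.04,37.92,-23.15,8.74
L02_f05,L02,159.01,52.42,-25.1,7.74
L02_f06,L02,127.74,28.35,-24.51,7.86
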