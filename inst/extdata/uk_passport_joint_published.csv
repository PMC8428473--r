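# Published national posterior-mean estimates (percent of population) of the
# joint distribution of change in vaccination inclination (y, 1-5) and
# baseline vaccination intent (z1-z4), UK April 2021 survey wave; one panel
# per passport variant. Worked-example input for net_shift_from_panels().
variant,y,z1,z2,z3,z4
domestic,1,1.88,1.03,0.87,2.62
domestic,2,0.68,0.59,0.66,2.15
domestic,3,1.74,2.84,6.71,35.2
domestic,4,0.10,0.29,1.45,13.1
domestic,5,0.10,0.31,2.03,25.7
international,1,1.62,0.77,0.73,2.49
international,2,0.70,0.51,0.59,2.14
international,3,1.90,2.85,6.03,31.18
international,4,0.14,0.41,1.61,12.72
international,5,0.16,0.52,2.76,30.17
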