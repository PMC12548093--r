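replicate_id,time_min,n2o_nmol,d15n_bulk,d15n_alpha,d18o
R1,42.9124,1029.897,-47.1444,-46.2504,-21.9045
R1,75.0967,1802.3197,-47.3582,-45.8526,-21.1419
R1,107.3024,2575.2574,-46.0217,-43.8465,-18.368
R1,139.4867,3347.6802,-44.842,-43.9245,-15.3687
R2,53.6405,1287.3712,-48.2838,-46.4915,-22.4923
R2,85.8247,2059.794,-46.9397,-47.3619,-21.3417
R2,118.0305,2832.7317,-45.9447,-46.2872,-18.3263
R2,150.2148,3605.1544,-44.437,-42.5302,-14.9344
R3,47.2036,1132.8867,-46.7873,-46.8862,-22.4342
R3,81.5335,1956.8043,-47.1274,-45.2956,-21.5773
R3,111.5936,2678.2471,-46.2043,-44.2833,-19.1065
R3,141.6323,3399.175,-45.962,-43.0555,-16.7499
R3,158.7972,3811.1338,-44.1753,-43.5304,-15.907
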