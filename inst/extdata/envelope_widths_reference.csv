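species,cell_type,cell_1,cell_2,cell_3,cell_4,cell_5,average_nm
B. subtilis,VEG,63.2,41.6,29.4,39.8,49.6,44.72
B. subtilis,SPO,237,180.6,225.5,209.2,216.2,213.70
S. violaceoruber,VEG,40,50,31,27.4,33,36.28
S. violaceoruber,SPO,97.4,67.8,92.2,107,119.4,96.76
M. xanthus,VEG,26.6,30,34.8,33,30.8,31.04
M. xanthus,SPO,249.6,246.6,272.8,177.4,269.8,243.24
A. cylindrica,VEG,63,50,70.6,51.6,58.4,58.72
A. cylindrica,SPO,199,230,210,207,238,216.80
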