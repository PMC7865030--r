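# demo configuration for `agedecomp simulate`: a compact demographic
# transition with a fertility decline centred on 1930 and an emigration
# wave in the 1880s
years: [1880, 1990]
tfr_start: 4.5
tfr_end: 1.8
tfr_midyear: 1930
tfr_width: 8
e0_start: 45
e0_end: 75
e0_midyear: 1925
e0_width: 20
initial_total: 1.0e6
burn_in: 150
migration_events:
  - years: [1882, 1883, 1884, 1885, 1886, 1887, 1888]
    amplitude: -0.004
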