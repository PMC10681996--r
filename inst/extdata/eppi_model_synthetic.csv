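# transform: log2p1
# intercept: 0.0
gene,coefficient
EPPI_G01,0.2761
EPPI_G02,-0.2824
EPPI_G03,0.1001
EPPI_G04,-0.2525
EPPI_G05,-0.1997
EPPI_G06,0.1653
EPPI_G07,0.2262
EPPI_G08,0.0577
EPPI_G09,0.204
EPPI_G10,-0.2174
EPPI_G11,0.1482
EPPI_G12,0.2214
EPPI_G13,0.2817
EPPI_G14,0.0915
EPPI_G15,0.1494
EPPI_G16,-0.2832
EPPI_G17,-0.2939
EPPI_G18,-0.0529
EPPI_G19,0.153
EPPI_G20,0.1769
EPPI_G21,0.2731
EPPI_G22,-0.0588
EPPI_G23,0.2969
EPPI_G24,-0.2851
EPPI_G25,0.0431
EPPI_G26,-0.164
EPPI_G27,0.1293
EPPI_G28,0.2736
EPPI_G29,-0.1452
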