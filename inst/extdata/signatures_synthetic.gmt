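EPPI_SET	synthetic ECM-related 29-gene set	EPPI_G01	EPPI_G02	EPPI_G03	EPPI_G04	EPPI_G05	EPPI_G06	EPPI_G07	EPPI_G08	EPPI_G09	EPPI_G10	EPPI_G11	EPPI_G12	EPPI_G13	EPPI_G14	EPPI_G15	EPPI_G16	EPPI_G17	EPPI_G18	EPPI_G19	EPPI_G20	EPPI_G21	EPPI_G22	EPPI_G23	EPPI_G24	EPPI_G25	EPPI_G26	EPPI_G27	EPPI_G28	EPPI_G29
NOISE_SIG_A	synthetic 10-gene noise set	NOISE_G001	NOISE_G002	NOISE_G003	NOISE_G004	NOISE_G005	NOISE_G006	NOISE_G007	NOISE_G008	NOISE_G009	NOISE_G010
NOISE_SIG_B	synthetic 15-gene noise set	NOISE_G011	NOISE_G012	NOISE_G013	NOISE_G014	NOISE_G015	NOISE_G016	NOISE_G017	NOISE_G018	NOISE_G019	NOISE_G020	NOISE_G021	NOISE_G022	NOISE_G023	NOISE_G024	NOISE_G025
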