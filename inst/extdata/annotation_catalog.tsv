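# Default protein annotation catalog: proteins named in the study's figures and text.
# Users supply complete catalogs for real data; the synthetic generator builds its own.
protein_id	gene_model	rp_class	family	paralog	marker_role	paralog_specific
RPL3A	AT1G43170	RP60S	uL3	RPL3A	none	TRUE
RPL3B	AT1G61580	RP60S	uL3	RPL3B	none	TRUE
RPL7aB	AT3G62870	RP60S	eL8	RPL7aB	none	TRUE
RPL10A	AT1G14320	RP60S	uL16	RPL10A	none	TRUE
RPL10C	AT3G11250	RP60S	uL16	RPL10C	none	TRUE
RPL10aB	AT2G27530	RP60S	uL1	RPL10aB	none	TRUE
RPL12C	AT5G60670	RP60S	uL11	RPL12C	none	FALSE
RPL13aD	AT5G48760	RP60S	uL13	RPL13aD	none	TRUE
RPL24B	AT3G53020	RP60S	eL24	RPL24B	none	TRUE
RPL26A	AT3G49910	RP60S	uL24	RPL26A	none	TRUE
RPL30C	AT3G18740	RP60S	eL30	RPL30C	none	FALSE
RPL37aC	AT3G60245	RP60S	eL43	RPL37aC	none	TRUE
RPP0B	AT3G09200	RP60S	uL10	RPP0B	none	TRUE
RPP0C	AT3G11964	RP60S	uL10	RPP0C	none	TRUE
RPP1A	AT1G01100	RP60S	P1/P2	RPP1A	none	TRUE
RPP1B	AT4G00810	RP60S	P1/P2	RPP1B	none	TRUE
RPP1C	AT5G47700	RP60S	P1/P2	RPP1C	none	TRUE
RPP2D	AT3G44590	RP60S	P1/P2	RPP2D	none	TRUE
eIF6A	AT3G55620	biogenesis	TIF6	eIF6A	pre60S_marker	TRUE
NMD3	AT2G03820	biogenesis	NMD3	NMD3	pre60S_marker	TRUE
RPL24C	AT2G44860	biogenesis	eL24	RPL24C	none	TRUE
eIF3C1	AT3G56150	eIF3	eIF3C	eIF3C1	preinit_marker	FALSE
eIF3C2	AT3G22860	eIF3	eIF3C	eIF3C2	preinit_marker	FALSE
eIF3G2	AT5G06000	eIF3	eIF3G	eIF3G2	preinit_marker	TRUE
LEA_AT5G60530	AT5G60530	other	LEA	LEA_AT5G60530	none	TRUE
R3H_AT1G03250	AT1G03250	other	R3H	R3H_AT1G03250	none	TRUE
NUC2	AT3G18610	other	nucleolin	NUC2	none	TRUE
PISTILLATA	AT5G20240	other	MADS	PISTILLATA	none	TRUE
FBOX_AT1G64540	AT1G64540	other	F-box	FBOX_AT1G64540	none	TRUE
FBOX_AT3G44120	AT3G44120	other	F-box	FBOX_AT3G44120	none	TRUE
MATH_AT3G29580	AT3G29580	other	MATH	MATH_AT3G29580	none	TRUE
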