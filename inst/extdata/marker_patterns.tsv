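# Allele presence/absence patterns of the eleven assayed candidate
# markers over the 24-individual panel (father, mother, 12 pink-banded,
# 10 yellow-unbanded). '1' present, '0' absent, 'x' sequence-absent but
# PCR-confirmed. Assay metadata retained as annotation only.
# For Cne_RAD11 the printed pattern follows the assay SNP (colour
# phase); the tag polymorphism itself is in phase with banding.
marker	allele	role	assay_phase	pattern	assay
Cne_RAD01	Unbanded	in_phase	banding	100000000010011111111111	CAPS RsaI
Cne_RAD01	Banded	alternative	banding	111111111111111111111111	CAPS RsaI
Cne_RAD02	Unbanded	in_phase	banding	10000000000000111x111111	CAPS AvaII
Cne_RAD02	Banded	alternative	banding	11111111111111xxx1111111	CAPS AvaII
Cne_RAD03	Unbanded	in_phase	banding	100000010000011111111111	Indel
Cne_RAD03	Banded	alternative	banding	111111111111111111111111	Indel
Cne_RAD04	Unbanded	in_phase	banding	100100000000001111111011	CAPS MspA1I
Cne_RAD04	Banded	alternative	banding	111111111111111111111111	CAPS MspA1I
Cne_RAD05	Pink	in_phase	colour	101011111111110000000000	CAPS AluI
Cne_RAD05	Yellow	alternative	colour	11x11x11xx1111x111111111	CAPS AluI
Cne_RAD06	Pink	in_phase	colour	101111111101100000000000	CAPS DdeI
Cne_RAD06	Yellow	alternative	colour	11x111111x1x111111111111	CAPS DdeI
Cne_RAD07	Pink	in_phase	colour	101011111111110000000100	CAPS DraI
Cne_RAD07	Yellow	alternative	colour	111111111111111111111111	CAPS DraI
Cne_RAD08	Unbanded	in_phase	banding	100000000000001111111111	CAPS HinfI
Cne_RAD08	Banded	alternative	banding	x11111111111111111111111	CAPS HinfI
Cne_RAD09	Unbanded	in_phase	banding	100000000000001111111111	CAPS BstUI
Cne_RAD09	Banded	alternative	banding	111111111x1111x111111111	CAPS BstUI
Cne_RAD10	Unbanded	in_phase	banding	100000000000001111111111	CAPS DpnII
Cne_RAD10	Banded	alternative	banding	x1x111111111111111111111	CAPS DpnII
Cne_RAD11	Pink	in_phase	colour	101111111101100000000000	CAPS BstUI
Cne_RAD11	Yellow	alternative	colour	111111111111111111111111	CAPS BstUI
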