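taxon	coord_start	coord_end	sequence	free_energy
Phoenix	38667	38729	ATCGAACCCATATGAAGTCTTACCATGAGCGGATTGTATCCATTGGGCAAATATGGGTTCGAT	-11.12
Phalaenopsis	39524	39586	ATCGAACCCATACGAAGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATGGGTTCGAT	-11.39
Oncidium	37640	37702	ATCGAACCCATACGAAGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATGGGTTCGAT	-11.39
Typha	40779	40839	ATCGAACCCATATGAAGTTTTACCATGAGCAGATTGTATCCATTGGGCAAATATGGGTTCGAT	-10.05
Brachypodium	37341	37403	ATCGAACCCATATGTCGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-9.14
Festuca	37657	37719	ATCGAACCCATATGTCGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-9.14
Hordeum	38178	38240	ATCGAACCCATATGTCGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-9.14
Lolium	37293	37355	ATCGAACCCATATGTCGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-9.14
Triticum	38014	38076	ATCGAACCCATATGTCGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-9.14
Agrostis	37863	37925	ATCGAACCCATACGTCGTCTTGCCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-7.31
Dioscorea	37740	37802	ATCGAACCCATATGAAGTCTTACCATGAGCAGATTGTATCCATTGGGCAAATATGGGTTCAAT	-7.06
Anomochloa	39677	39739	ATCGAACCCATATGTCGTCTTACCATGAGCGGATTGTATCCATTGGGCAAATATAGGTTCGAT	-6.12
Oryza.niv	37482	37544	ATCGAACCCATATGTCGTCTTACCATGAGCCGATTGTATCCATTGAGCAAATATAGGTTCGAT	-5.95
Oryza.sat	37548	37610	ATCGAACCCATATGTCGTCTTACCATGAGCCGATTGTATCCATTGAGCAAATATAGGTTCGAT	-5.95
Bambusa	39617	39679	ATCGAACCCATATGTCGTCTTACCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-5.2
Coix	39617	39679	ATCGAACCCATATGTCGTCTTACCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-5.2
Dendrocalamus	39782	39844	ATCGAACCCATATGTCGTCTTACCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-5.2
Saccharum	40453	40515	ATCGAACCCATATGTCGTCTTACCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-5.2
Sorghum	40672	40734	ATCGAACCCATATGTCGTCTTACCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCGAT	-5.2
Zea	39899	39961	ATCGAACCCATATGTCGTCTTACCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCAAT	-2.06
Lemna	41245	41307	ATCAAACCCATATGAAGTCTTCCCATGAGCAGATTGTATCCATTGGGCAAATATAGGTTCAAT	-1.49
Acorus.ame	38253	38314	ATCAAACCCATATAAAGTCTTACCATGAGCGGATTGTATCCACTGGGCAAATATAGGTTCAAT	-1.1
Acorus.cal	38245	38307	ATCAAACCCATATAAAGTCTTACCATGAGCGGATTGTATCCACTGGGCAAATATAGGTTCAAT	-1.1
Panax	40104	40166	ATCGAAACCATATGAAGTTTTACCATGTGCGGATTGTATCCATTGAGCAAATATAGGTTCGAT	NA
Nicotiana	39789	39851	ATCGAAACCATATGAAGTTTTACCATGAGCGGATTGTATCCATTGAGCAAATATAGGTTCAAT	NA
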