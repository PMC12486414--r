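accession	domain	source	phylum	class	order	family	genus
NIRK0001	Bacteria	marine sediment	Pseudomonadota	Alphaproteobacteria	NA	NA	NA
NIRK0002	Bacteria	marine water column	Pseudomonadota	Alphaproteobacteria	NA	NA	NA
NIRK0003	Bacteria	marine sediment	NA	NA	NA	NA	NA
NIRK0004	Archaea	aquatic other	Euryarchaeota	Halobacteria	NA	NA	NA
NIRK0005	Archaea	aquatic other	Euryarchaeota	Halobacteria	NA	NA	NA
NIRK0006	Bacteria	wastewater	NA	NA	NA	NA	NA
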