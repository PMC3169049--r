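virus_taxon	host_taxon
virus01	host01
virus02	host02
virus03	host03
virus04	host04
virus05	host05
virus06	host06
virus07	host07
virus08	host08
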