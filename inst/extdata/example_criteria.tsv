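# Example phylogenetic diversity criteria (synthetic example, not taken
# from any published study): one line per named species set.
# set_name	species (comma separated)	min_present
cladeA	sp01,sp02,sp03,sp04	3
cladeB	sp05,sp06,sp07,sp08	3
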