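# Mini-table of named plant cis-regulatory elements for promoter scans.
# IUPAC definitions entered from the public PLACE database records
# (Higo et al. 1999, Nucleic Acids Research 27:297-300; PLACE signal scan
# motif entries). This is a small curated subset, not a redistribution of
# the PLACE database.
element_id	iupac
CACTFTPPCA1	YACT
EBOXBNNAPA	CANNTG
DOFCOREZM	AAAG
MYCCONSENSUSAT	CANNTG
CAATBOX1	CAAT
GTGANTG10	GTGA
WRKY71OS	TGAC
GT1CONSENSUS	GRWAAW
ROOTMOTIFTAPOX1	ATATT
POLLEN1LELAT52	AGAAA
MYBCORE	CNGTTR
OSE2ROOTNODULE	CTCTT
ACGTCBOX	GACGTC
TATABOX3	TATTAAT
CTRMCAMV35S	TCTCTCTCT
HDZIP2ATATHB2	TAATMATTA
CANBNNAPA	CNAACAC
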