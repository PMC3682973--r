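# Yersinia pseudotuberculosis serotypes with known O-unit first sugar and
# gnu (UndPP-GlcNAc 4-epimerase) gene presence, as enumerated in the
# published clade-D discussion. gnu presence correlates absolutely with
# GalNAc as first sugar across these serotypes.
serotype	gnu_present	first_sugar	in_tree
O6	TRUE	GalNAc	TRUE
O7	TRUE	GalNAc	TRUE
O3	TRUE	GalNAc	TRUE
O10	TRUE	GalNAc	TRUE
O15	TRUE	GalNAc	TRUE
O1c	TRUE	GalNAc	FALSE
O2b	TRUE	GalNAc	FALSE
O2c	TRUE	GalNAc	FALSE
O4a	TRUE	GalNAc	FALSE
O5a	TRUE	GalNAc	FALSE
O5b	TRUE	GalNAc	FALSE
O1b	FALSE	GlcNAc	FALSE
O11	FALSE	GlcNAc	FALSE
O12	FALSE	GlcNAc	FALSE
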