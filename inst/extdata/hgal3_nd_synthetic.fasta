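>hGal3_ND_synthetic residues 1-112, reconstruction of the galectin-3 N-terminal domain repeat architecture (UniProtKB P17931)
MADNFSLHDALSGSGNPNPQGWPGAWGNQPAGAGGYPGASYPGAYPGQAP
PGAYPGQAPPGAYPGAPGAYPGAPAPGVYPGPPSGPGAYPSSGQPSAPGA
YPATGPYGAPAG
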