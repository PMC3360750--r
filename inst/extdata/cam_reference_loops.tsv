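# Reference calcium-binding loop set: the four Ca2+-coordination loops of the
# canonical vertebrate calmodulin. The vertebrate calmodulin protein is 100%
# identical across vertebrates, so the same four loops are listed once per
# species (40 loops in total). Replace this file (same two columns) to use a
# different reference set; non-vertebrate calmodulin loops diverge and can be
# added by the user from a trusted source.
# Columns: label = organism / loop index, loop = 12-residue coordination loop.
label	loop
Homo_sapiens_CaM_loop1	DKDGDGTITTKE
Homo_sapiens_CaM_loop2	DADGNGTIDFPE
Homo_sapiens_CaM_loop3	DKDGNGYISAAE
Homo_sapiens_CaM_loop4	DIDGDGQVNYEE
Mus_musculus_CaM_loop1	DKDGDGTITTKE
Mus_musculus_CaM_loop2	DADGNGTIDFPE
Mus_musculus_CaM_loop3	DKDGNGYISAAE
Mus_musculus_CaM_loop4	DIDGDGQVNYEE
Rattus_norvegicus_CaM_loop1	DKDGDGTITTKE
Rattus_norvegicus_CaM_loop2	DADGNGTIDFPE
Rattus_norvegicus_CaM_loop3	DKDGNGYISAAE
Rattus_norvegicus_CaM_loop4	DIDGDGQVNYEE
Gallus_gallus_CaM_loop1	DKDGDGTITTKE
Gallus_gallus_CaM_loop2	DADGNGTIDFPE
Gallus_gallus_CaM_loop3	DKDGNGYISAAE
Gallus_gallus_CaM_loop4	DIDGDGQVNYEE
Xenopus_laevis_CaM_loop1	DKDGDGTITTKE
Xenopus_laevis_CaM_loop2	DADGNGTIDFPE
Xenopus_laevis_CaM_loop3	DKDGNGYISAAE
Xenopus_laevis_CaM_loop4	DIDGDGQVNYEE
Danio_rerio_CaM_loop1	DKDGDGTITTKE
Danio_rerio_CaM_loop2	DADGNGTIDFPE
Danio_rerio_CaM_loop3	DKDGNGYISAAE
Danio_rerio_CaM_loop4	DIDGDGQVNYEE
Bos_taurus_CaM_loop1	DKDGDGTITTKE
Bos_taurus_CaM_loop2	DADGNGTIDFPE
Bos_taurus_CaM_loop3	DKDGNGYISAAE
Bos_taurus_CaM_loop4	DIDGDGQVNYEE
Oryctolagus_cuniculus_CaM_loop1	DKDGDGTITTKE
Oryctolagus_cuniculus_CaM_loop2	DADGNGTIDFPE
Oryctolagus_cuniculus_CaM_loop3	DKDGNGYISAAE
Oryctolagus_cuniculus_CaM_loop4	DIDGDGQVNYEE
Sus_scrofa_CaM_loop1	DKDGDGTITTKE
Sus_scrofa_CaM_loop2	DADGNGTIDFPE
Sus_scrofa_CaM_loop3	DKDGNGYISAAE
Sus_scrofa_CaM_loop4	DIDGDGQVNYEE
Equus_caballus_CaM_loop1	DKDGDGTITTKE
Equus_caballus_CaM_loop2	DADGNGTIDFPE
Equus_caballus_CaM_loop3	DKDGNGYISAAE
Equus_caballus_CaM_loop4	DIDGDGQVNYEE
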