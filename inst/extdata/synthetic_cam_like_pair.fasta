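>synthetic_camlike_A synthetic calmodulin-like demo sequence (constructed, not a natural protein)
KFQLKCYHAPVCHWTMGCKDKDGDGTITTKERQHWLTRTKVHMVPGHGGWKADADGNGTIDFPEMTTKHKKFHVFKTFPIYPTRVVYDKDGNGYISAAEKAPCQMFCGKKCFIAFLAFCCDIDGDGQVNYEEPQMHLKAKCMYLM
>synthetic_camlike_B synthetic diverged partner of synthetic_camlike_A (constructed, not a natural protein)
KFQTKCQWWPVEHWTCKWCDKDGDGTITTKEYQHWARRMLVHKVGGHGWFKADADGNGTIDFPEMTVMHYKFYVFKTLPIYPTAIVYDKDGNGYISAAEAAPHQMDCGKSCFIALMDFCRDIDGDGQVNYEENQNHLKAKEWYLM
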