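count	b1	c2	class
52	DTGAD	GRDLL	active
17	DTGVD	GRDLL	active
4	DTRAD	GRDLL	potential
1	DTVVD	GRDLL	potential
1	DTGDD	GRDLL	potential
4	DTEAD	GRDLL	potential
1	DTVAD	GRDLL	potential
1	DTGAN	GRDLL	potential
3	DTGSD	GRDLL	potential
1	DTGVD	GRHLL	potential
1	DTGAN	GKDLL	potential
3	DTGED	GRDLL	potential
1	DTGVD	GKDLL	potential
1	DTGAD	GRELL	potential
3	DTGAD	GQDLL	potential
1	DTGTD	GRDLL	potential
1	DTGAD	GRDIL	potential
3	DTGAD	GKDLL	potential
1	DTGMD	GRDLL	potential
1	DTGAD	GQELL	potential
3	DTDAD	GRDLL	potential
1	DTGID	GRDLL	potential
1	DTAAD	GRDLL	potential
2	DTEVD	GRDLL	potential
1	DTGGD	GRDLL	potential
4	DTGAD	RRDLL	inactive
1	DTRSD	GRDLL	inactive
1	DTGAD	GHLL	inactive
3	DTGAD	ERDLL	inactive
1	DTRMD	GKEIY	inactive
1	DTEAD	GQDLL	inactive
2	HTGAD	GRDLL	inactive
1	DTRAD	GWDPL	inactive
1	DRGMD	GRDLL	inactive
2	DTVVD	GGTLL	inactive
1	DTGVD	LSPHTFI	inactive
1	DMGAD	DQDLL	inactive
2	WAWAV	GWDLL	inactive
1	DTGVA	GRDLL	inactive
1	DMGAD		inactive
1	VTGVD	GRDLL	inactive
1	DTGPD		inactive
1	DIGVD	GRDLL	inactive
1	ITWGR	GVDN	inactive
1	DTGVD	RRDLL	inactive
1	DIGAD	GGDLL	inactive
1		GWDLL	inactive
1	DTGAD	VWDLL	inactive
1	DIGAD	ERDLLL	inactive
1	ETGVD	GWDLL	inactive
1	DTGAD	GVDLL	inactive
1	DAGAD	GRDLL	inactive
1	DTVAD	GGDLL	inactive
1	DTGAD	GTRPI	inactive
1	ATGAD	GRDLL	inactive
1	DTRTD	GRDVL	inactive
1	DTGAD	GRYLL	inactive
1	ALGAD	RRDLL	inactive
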