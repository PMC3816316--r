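source	version	n_genes	n_isoforms	n_exons
AceView	2010	72376	259426	678503
H-InvDB	8.0	43893	236861	542099
Ensembl	67	48817	177858	534400
Vega	48	44880	158835	493509
UCSC	-	28423	75725	273711
RefSeq	-	23731	41099	227710
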