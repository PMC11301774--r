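>synthetic|heavy|V|IGHV-syn1
QVQLVQSGAEVKKPGASVKVSCKASGYTFTSYAMHWVRQAPGQGLEWMGWINAGNGNTKYSQKFQGRVTMTRDTSISTAYMELSRLRSDDTAVYYCAR
>synthetic|heavy|V|IGHV-syn2
EVQLVESGGGLVQPGGSLRLSCAASGFTFSSYWMSWVRQAPGKGLEWVANIKQDGSEKYYVDSVKGRFTISRDNAKNSLYLQMNSLRAEDTAVYYCAR
>synthetic|heavy|J|IGHJ-syn1
WGQGTLVTVSS
>synthetic|heavy|C|IGHC-syn1
ASTKGPSVFPLAPSSKSTSG
>synthetic|light|V|IGKV-syn1
DIQMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIYAASSLQSGVPSRFSGSGSGTDFTLTISSLQPEDFATYYCQQSYSTP
>synthetic|light|J|IGKJ-syn1
FGQGTKVEIK
>synthetic|light|C|IGKC-syn1
RTVAAPSVFIFPPSD
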