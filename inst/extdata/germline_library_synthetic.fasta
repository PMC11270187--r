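>IGHV4-59|heavy|approximate *01 allele, curated from general knowledge; verify against IMGT before laboratory use
QVQLQESGPGLVKPSETLSLTCTVSGGSISSYYWSWIRQPPGKGLEWIGYIYYSGSTNYNPSLKSRVTISVDTSKNQFSLKLSSVTAADTAVYYCAR
>IGHV2-26|heavy|approximate *01 allele, curated from general knowledge; verify against IMGT before laboratory use
QVTLKESGPVLVKPTETLTLTCTVSGFSLSNARMGVSWIRQPPGKALEWLAHIFSNDEKSYSTSLKSRLTISKDTSKSQVVLTMTNMDPVDTATYYCAR
>IGHV4-4|heavy|approximate *01 allele, curated from general knowledge; verify against IMGT before laboratory use
QVQLQESGPGLVKPSGTLSLTCAVSGGSISSSNWWSWVRQPPGKGLEWIGEIYHSGSTNYNPSLKSRVTISVDKSKNQFSLKLSSVTAADTAVYYCAR
>IGKV1-16|kappa|approximate *01 allele, curated from general knowledge; verify against IMGT before laboratory use
DIQMTQSPSSLSASVGDRVTITCRASQGISNYLAWFQQKPGKAPKSLIYAASSLQSGVPSRFSGSGSGTDFTLTISSLQPEDFATYYCQQYNSYP
>IGKV1-39|kappa|approximate *01 allele, curated from general knowledge; verify against IMGT before laboratory use
DIQMTQSPSSLSASVGDRVTITCRASQSISSYLNWYQQKPGKAPKLLIYAASSLQSGVPSRFSGSGSGTDFTLTISSLQPEDFATYYCQQSYSTP
>IGKV1-6|kappa|approximate *01 allele, curated from general knowledge; verify against IMGT before laboratory use
AIQMTQSPSSLSASVGDRVTITCRASQGIRNDLGWYQQKPGKAPKRLIYAASSLQSGVPSRFSGSGSGTEFTLTISSLQPEDFATYYCLQDYNYP
>IGHV2-9|heavy|synthetic murine-type framework (stand-in; carries K71/V78)
QVTLKESGPGILQPSQTLSLTCSFSGFSLSNYGVHWIRQPSGKGLEWLAVIWSGGSTDYNAAFISRLTISKDTSNSQVFLKITSVDTADTATYYCAR
>IGKV9-124|kappa|synthetic murine-type framework (stand-in; carries K60/R66)
DIVMTQSPSSLAVSAGEKVTMSCKSSQSLLNSRTRKNYLAWYQQKPGQSPKLLIYWASTRESGVPKRFSGSRSGTDFTLTISSVQAEDLAVYYCQQHYSTP
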