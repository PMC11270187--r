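>parental-VH|heavy|synthetic murine-type parental stand-in (K71/V78)
QVTLKESGPGILQPSQTLSLTCSFSGFSLSNYGVHWIRQPSGKGLEWLAVIWSGGSTDYNAAFISRLTISKDTSNSQVFLKITSVDTADTATYYCARDRGYYGSSFDYWGQGTLVTVSS
>parental-VL|kappa|synthetic murine-type parental stand-in (K60/R66)
DIVMTQSPSSLAVSAGEKVTMSCKSSQSLLNSRTRKNYLAWYQQKPGQSPKLLIYWASTRESGVPKRFSGSRSGTDFTLTISSVQAEDLAVYYCQQHYSTPRTFGGGTKLEIK
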