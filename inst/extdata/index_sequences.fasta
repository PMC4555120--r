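>VKORC1_HUMAN vitamin K epoxide reductase complex subunit 1, Homo sapiens (UniProt Q9BQB6, transcribed from the public record; 163 aa)
MGSTWGSPGWVRLALCLTGLVLSLYALHVKAARARDRDYRALCDVGTAISCSRVFSSRWG
RGFGLVEHVLGQDSILNQSNSIFGCIFYTLQLLLGCLRTRWASVLMLLSSLVSLAGSVYL
AWILFFVLYDFCIVCITTYAINVSLMWLSFRKVQEPQGKAKRH
>DSBB_ECOLI disulfide bond formation protein B, Escherichia coli K-12 (UniProt P0A6M2, transcribed from the public record; 176 aa)
MLRFLNQCSQGRGAWLLMAFTALALELTALWFQHVMLLKPCVLCIYERCALFGVLGAALI
GAIAPKTPLRYVAMVIWLYSAFRGVQLTYEHTMLQLYPSPFATCDFMVRFPEWLPLDKWV
PQVFVASGDCAERQWDFLGLEMPQWLLGIFIAYLIVAVLVVISQPFKAKKRDLFGR
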