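enzyme,observed,predicted
AluI,183,188
RsaI,74,80
RsaI,238,242
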