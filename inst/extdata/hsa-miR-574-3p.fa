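>hsa-miR-574-3p MIMAT0003239 mature sequence (miRBase)
CACGCUCAUGCACACACCCACA
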