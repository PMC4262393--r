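option,n
>0%,17
>25%,75
>50%,63
>75%,36
100%,1
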