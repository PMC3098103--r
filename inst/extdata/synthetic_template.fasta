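>SYNTH_TMPL synthetic adenylation-domain-like template
SPVHKKSIVVPSTENWYDGVPQQVMDSNVFRKVVWRFMNWECLFHVGPQDGKRHLHSFTI
YWTQTDDAHNLSQQQKDVFMYYPSCVGLHCSPEMPTGGCESVNSQNMRRGAVNDTKLLLR
EMHGMGNQFFPMSHLLSYHKPPTYRQPRIACCFAHCPFHFIDDKKPFLCHNGSNVNWFCT
TWINGFCLCCYDDNWAAQHEVVLHDAYPWRVWMKTDRPAANYIGDKRAALHDLWQKFRCL
ECFGYIKTYQKFDMMMDQSMVEGNPLKSIYAFFKPHGYCVVHTGHSMMWKKAPWEPMDTI
CSNELDVTNSKDFYILPDFILRNGFWGRSHPYPDGCMPKPGNGENMFTALDQTNREAHED
GPNQHEHSMVQEWSMTGMFRHSEKPSMHGHVNCCAENKIWPWGTERLDDQMPNNAQYLNQ
RGAQRSIYHA
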