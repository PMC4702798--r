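>consensus
KVLGQGSFGTVYKAILKVALRAMEVLREALNPLIVVTELMDLIATEYMGSLDLTRFLESILGAVKILHRDLAARNVLVAADFGLA
>SYN_TK1
KVLGQGSFGTVFKAILKVALRAMEVLREALNPLIVLTELMDLIAMEYMGSLDLTRFLESILGAVKILHRDLAARNVLVAADFGLA
>SYN_CMGC1
KVLGAGSFGTVYKAILKVALRAMDVLREALNPLIVVTELMDLIATEYMGSLDLTRFLESVLGAVKILHRDLAARNVLVAADFGLA
>SYN_STE1
KVLGQGSFGTVYKAILKVALRAMEVLREALNPLIVVTELMDLIAFEFMGSLDLTRFLESILGAVKILHRDIAARNVLVAADFGLA
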