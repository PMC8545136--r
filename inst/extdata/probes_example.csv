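probe_id,sequence,fluorophore,target
tetO_LNA,CTCTATCACTGATAGGGA,6-FAM,tetO operator array
xylUW_demo_01,ACGTTGCATCCAGTTGACGT,CAL Fluor Red 610,xylUW mRNA (synthetic example)
xylX_demo_01,TTGCCAGATCGTAACGGTCA,CAL Fluor Red 610,xylX mRNA (synthetic example)
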