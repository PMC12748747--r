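sample,target,strand,channel,treatment,ct,spike_ct
t05,plusC_top,top,FAM,mock,24.1,20.1
t05,plusC_top,top,FAM,alkali,28.42,20.1
t30,plusC_top,top,FAM,mock,23.05,20.3
t30,plusC_top,top,FAM,alkali,24.41,20.3
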