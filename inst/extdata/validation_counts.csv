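sample,coded_relevant,coded_irrelevant,total
retrieved,875,125,1000
not_retrieved,304,696,1000
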