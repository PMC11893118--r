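record_id,location_id,region,sowing,petal_fall,harvest,fresh_yield
s2101,gatton,SEQ,2021-02-19,2021-04-01,2021-04-22,12092
s2102,gatton,SEQ,2021-02-27,2021-04-08,2021-04-28,10578
s2103,gatton,SEQ,2021-01-15,2021-02-24,2021-03-18,9400
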