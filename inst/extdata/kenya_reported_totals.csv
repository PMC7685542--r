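period_type,period,cases
year,2016,155539
year,2017,171682
year,2018,263305
year,2019,295642
quarter,Q1,213350
quarter,Q2,222250
quarter,Q3,215273
quarter,Q4,235295
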