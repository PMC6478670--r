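"id","Childhood trauma","Ethnicity","Immigration","Premorbid IQ","Non-right handedness","Olfactory identification impairment","Clinical high risk state for psychosis","Urbanicity"
"1","Yes","Black Caribbean, Medium ethnic density area","Not immigrant",,,"No","<9","No"
"2",,"White","Not immigrant",">93.6","No","Yes",,
"3","No","White","Not immigrant","<93.6","No","No","<9","Yes"
"4","No",,"2nd generation immigrant, From other regions",">93.6","No","No","<9","Yes"
"5","No","Black Caribbean, High ethnic density area",,">93.6","No",,"<9","Yes"
"6","No","White","1st generation immigrant, From other regions",">93.6","No",,"<9","Yes"
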