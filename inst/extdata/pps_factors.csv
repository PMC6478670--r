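"factor","level","relative_risk","prevalence","baseline","evidence_class","instrument","cutoff"
"Childhood trauma","Yes",2.87,0.109,FALSE,"III","Childhood trauma questionnaire","Moderate to severe"
"Childhood trauma","No",1,0.891,TRUE,"III","Childhood trauma questionnaire","Moderate to severe"
"Ethnicity","Black Caribbean, Low ethnic density area",6.30957344480193,0.016,FALSE,"I","Self-defined","Non-white ethnicity"
"Ethnicity","Other non-white, Low ethnic density area",3.54813389233575,0.064,FALSE,"I","Self-defined","Non-white ethnicity"
"Ethnicity","Black Caribbean, Medium ethnic density area",5.62341325190349,0.04,FALSE,"I","Self-defined","Non-white ethnicity"
"Ethnicity","Other non-white, Medium ethnic density area",3.16227766016838,0.16,FALSE,"I","Self-defined","Non-white ethnicity"
"Ethnicity","Black Caribbean, High ethnic density area",3.54813389233576,0.024,FALSE,"I","Self-defined","Non-white ethnicity"
"Ethnicity","Other non-white, High ethnic density area",1.99526231496888,0.096,FALSE,"I","Self-defined","Non-white ethnicity"
"Ethnicity","White",1,0.6,TRUE,"I","Self-defined","Non-white ethnicity"
"Immigration","1st generation immigrant, From North Africa",2.23872113856834,0.025,FALSE,"II","Self-defined","First- or second-generation"
"Immigration","2nd generation immigrant, From North Africa",1.99526231496888,0.025,FALSE,"II","Self-defined","First- or second-generation"
"Immigration","1st generation immigrant, From other regions",1.77827941003892,0.075,FALSE,"II","Self-defined","First- or second-generation"
"Immigration","2nd generation immigrant, From other regions",1.58489319246111,0.075,FALSE,"II","Self-defined","First- or second-generation"
"Immigration","Not immigrant",1,0.8,TRUE,"II","Self-defined","First- or second-generation"
"Premorbid IQ","<93.6",2.12765957446809,0.335,FALSE,"II","National adult reading test","<93.6"
"Premorbid IQ",">93.6",1,0.665,TRUE,"II","National adult reading test","<93.6"
"Non-right handedness","Yes",1.58,0.1,FALSE,"III","Self-defined","Non-right handedness"
"Non-right handedness","No",1,0.9,TRUE,"III","Self-defined","Non-right handedness"
"Olfactory identification impairment","Yes",5.26315789473684,0.22,FALSE,"II","University of Pennsylvania smell identification test","Mild microsmia"
"Olfactory identification impairment","No",1,0.78,TRUE,"II","University of Pennsylvania smell identification test","Mild microsmia"
"Clinical high risk state for psychosis",">9",9.32,0.14,FALSE,"I","Prodromal questionnaire (16-item version)",">9"
"Clinical high risk state for psychosis","<9",1,0.86,TRUE,"I","Prodromal questionnaire (16-item version)",">9"
"Urbanicity","Yes",2.2,0.736,FALSE,"I","Population density of local authority","Urban center of at least 50,000 inhabitants"
"Urbanicity","No",1,0.264,TRUE,"I","Population density of local authority","Urban center of at least 50,000 inhabitants"
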