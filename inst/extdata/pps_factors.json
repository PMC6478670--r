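{"provenance":"PPS prototype defaults; urbanicity prevalence is a reported population value, remaining prevalences and composite component relative risks are approximate (reverse-engineered from the published half-integer scores)","factors":[{"name":"Childhood trauma","instrument":"Childhood trauma questionnaire","cutoff":"Moderate to severe","levels":[{"label":"Yes","relative_risk":2.87,"prevalence":0.109,"baseline":false,"evidence_class":"III"},{"label":"No","relative_risk":1,"prevalence":0.891,"baseline":true,"evidence_class":"III"}]},{"name":"Ethnicity","instrument":"Self-defined","cutoff":"Non-white ethnicity","levels":[{"label":"Black Caribbean, Low ethnic density area","relative_risk":6.30957344480193,"prevalence":0.016,"baseline":false,"evidence_class":"I","components":{"Black Caribbean":3.54813389233576,"Low ethnic density area":1.77827941003892}},{"label":"Other non-white, Low ethnic density area","relative_risk":3.54813389233575,"prevalence":0.064,"baseline":false,"evidence_class":"I","components":{"Other non-white":1.99526231496888,"Low ethnic density area":1.77827941003892}},{"label":"Black Caribbean, Medium ethnic density area","relative_risk":5.62341325190349,"prevalence":0.04,"baseline":false,"evidence_class":"I","components":{"Black Caribbean":3.54813389233576,"Medium ethnic density area":1.58489319246111}},{"label":"Other non-white, Medium ethnic density area","relative_risk":3.16227766016838,"prevalence":0.16,"baseline":false,"evidence_class":"I","components":{"Other non-white":1.99526231496888,"Medium ethnic density area":1.58489319246111}},{"label":"Black Caribbean, High ethnic density area","relative_risk":3.54813389233576,"prevalence":0.024,"baseline":false,"evidence_class":"I","components":{"Black Caribbean":3.54813389233576,"High ethnic density area":1}},{"label":"Other non-white, High ethnic density area","relative_risk":1.99526231496888,"prevalence":0.096,"baseline":false,"evidence_class":"I","components":{"Other non-white":1.99526231496888,"High ethnic density area":1}},{"label":"White","relative_risk":1,"prevalence":0.6,"baseline":true,"evidence_class":"I","components":{"White":1}}]},{"name":"Immigration","instrument":"Self-defined","cutoff":"First- or second-generation","levels":[{"label":"1st generation immigrant, From North Africa","relative_risk":2.23872113856834,"prevalence":0.025,"baseline":false,"evidence_class":"II","components":{"1st generation immigrant":1.77827941003892,"From North Africa":1.25892541179417}},{"label":"2nd generation immigrant, From North Africa","relative_risk":1.99526231496888,"prevalence":0.025,"baseline":false,"evidence_class":"II","components":{"2nd generation immigrant":1.58489319246111,"From North Africa":1.25892541179417}},{"label":"1st generation immigrant, From other regions","relative_risk":1.77827941003892,"prevalence":0.075,"baseline":false,"evidence_class":"II","components":{"1st generation immigrant":1.77827941003892,"From other regions":1}},{"label":"2nd generation immigrant, From other regions","relative_risk":1.58489319246111,"prevalence":0.075,"baseline":false,"evidence_class":"II","components":{"2nd generation immigrant":1.58489319246111,"From other regions":1}},{"label":"Not immigrant","relative_risk":1,"prevalence":0.8,"baseline":true,"evidence_class":"II","components":{"Not immigrant":1}}]},{"name":"Premorbid IQ","instrument":"National adult reading test","cutoff":"<93.6","levels":[{"label":"<93.6","relative_risk":2.12765957446809,"prevalence":0.335,"baseline":false,"evidence_class":"II"},{"label":">93.6","relative_risk":1,"prevalence":0.665,"baseline":true,"evidence_class":"II"}]},{"name":"Non-right handedness","instrument":"Self-defined","cutoff":"Non-right handedness","levels":[{"label":"Yes","relative_risk":1.58,"prevalence":0.1,"baseline":false,"evidence_class":"III"},{"label":"No","relative_risk":1,"prevalence":0.9,"baseline":true,"evidence_class":"III"}]},{"name":"Olfactory identification impairment","instrument":"University of Pennsylvania smell identification test","cutoff":"Mild microsmia","levels":[{"label":"Yes","relative_risk":5.26315789473684,"prevalence":0.22,"baseline":false,"evidence_class":"II"},{"label":"No","relative_risk":1,"prevalence":0.78,"baseline":true,"evidence_class":"II"}]},{"name":"Clinical high risk state for psychosis","instrument":"Prodromal questionnaire (16-item version)","cutoff":">9","levels":[{"label":">9","relative_risk":9.32,"prevalence":0.14,"baseline":false,"evidence_class":"I"},{"label":"<9","relative_risk":1,"prevalence":0.86,"baseline":true,"evidence_class":"I"}]},{"name":"Urbanicity","instrument":"Population density of local authority","cutoff":"Urban center of at least 50,000 inhabitants","levels":[{"label":"Yes","relative_risk":2.2,"prevalence":0.736,"baseline":false,"evidence_class":"I"},{"label":"No","relative_risk":1,"prevalence":0.264,"baseline":true,"evidence_class":"I"}]}]}
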