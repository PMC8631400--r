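tissue	accession	parent_name	source	n_children	n_genes	n_immune
adipose	GO:0070162	adiponectin secretion	ontology	2	6	3
adipose	GO:0060612	adipose tissue development	ontology	4	38	19
adipose	GO:0005901	caveola	ontology	5	83	30
adipose	GO:1904606	fat cell apoptotic process	ontology	1	1	1
adipose	GO:0045444	fat cell differentiation	ontology	9	213	94
adipose	GO:0070341	fat cell proliferation	ontology	2	10	2
adipose	GO:0044321	response to leptin	ontology	5	24	11
adipose	HPA	additional from atlas	atlas	NA	69	29
liver	GO:0034382	chylomicron remnant clearance	ontology	1	8	3
liver	GO:0002384	hepatic immune response	ontology	1	2	2
liver	GO:0035733	hepatic stellate cell activation	ontology	2	6	3
liver	GO:0061868	hepatic stellate cell migration	ontology	1	2	1
liver	GO:1990922	hepatic stellate cell proliferation	ontology	1	2	1
liver	GO:0097284	hepatocyte apoptotic process	ontology	1	12	6
liver	GO:0001889	liver development	ontology	5	130	60
liver	GO:0034379	very-low-density lipoprotein particle assembly	ontology	1	12	3
liver	HPA	additional from atlas	atlas	NA	326	131
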