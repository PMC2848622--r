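<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic example lexicon in minimal SKOS RDF/XML (not real curated data). -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:skos="http://www.w3.org/2004/02/skos/core#">
  <skos:Concept rdf:about="http://example.org/chem/EX001">
    <skos:prefLabel>aspirin</skos:prefLabel>
    <skos:altLabel>acetylsalicylic acid</skos:altLabel>
    <skos:notation rdf:datatype="http://example.org/datatype#CAS">50-78-2</skos:notation>
    <skos:notation rdf:datatype="http://example.org/datatype#InChI">InChI=1S/C9H8O4/c1-6(10)13-8-5-3-2-4-7(8)9(11)12/h2-5H,1H3,(H,11,12)</skos:notation>
  </skos:Concept>
  <skos:Concept rdf:about="http://example.org/chem/EX002">
    <skos:prefLabel>sodium chloride</skos:prefLabel>
    <skos:altLabel>NaCl</skos:altLabel>
    <skos:notation rdf:datatype="http://example.org/datatype#CAS">7647-14-5</skos:notation>
  </skos:Concept>
</rdf:RDF>
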