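@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .
@prefix gbol: <http://gbol.life/0.1/> .

gbol:chr1
    a gbol:Sequence ;
    gbol:sequence "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT" ;
    gbol:strandType gbol:DoubleStrandedDNA ;
    gbol:feature gbol:Feature_2, gbol:Feature_8, gbol:Feature_14 .

gbol:AutomaticAnnotationActivity_1
    a gbol:AutomaticAnnotationActivity ;
    gbol:softwareAgent <http://example.org/tool/toytool> ;
    gbol:parameters "--mode fast --toy" ;
    gbol:inputFile "file:///data/toy_genome.fasta"^^xsd:anyURI ;
    gbol:outputFile "file:///data/toy_genome.gff3"^^xsd:anyURI .

gbol:Feature_2
    a gbol:Feature ;
    gbol:locus "TOY_0001" ;
    gbol:featureType "gene" ;
    gbol:location gbol:Region_3 ;
    gbol:provenance gbol:FeatureProvenance_7 .

gbol:Region_3
    a gbol:Region ;
    gbol:reference gbol:chr1 ;
    gbol:begin gbol:ExactPosition_4 ;
    gbol:end gbol:ExactPosition_5 .

gbol:ExactPosition_4
    a gbol:ExactPosition ;
    gbol:position "100"^^xsd:integer .

gbol:ExactPosition_5
    a gbol:ExactPosition ;
    gbol:position "400"^^xsd:integer .

gbol:ProvenanceAnnotation_6
    a gbol:ProvenanceAnnotation ;
    gbol:experiment <http://purl.obolibrary.org/obo/ECO_0000203> .

gbol:FeatureProvenance_7
    a gbol:FeatureProvenance ;
    gbol:onProperty gbol:featureType ;
    gbol:annotation gbol:ProvenanceAnnotation_6 ;
    gbol:origin gbol:AutomaticAnnotationActivity_1 .

gbol:Feature_8
    a gbol:Feature ;
    gbol:locus "TOY_0002" ;
    gbol:featureType "CDS" ;
    gbol:location gbol:Region_9 ;
    gbol:provenance gbol:FeatureProvenance_13 .

gbol:Region_9
    a gbol:Region ;
    gbol:reference gbol:chr1 ;
    gbol:begin gbol:ExactPosition_10 ;
    gbol:end gbol:ExactPosition_11 ;
    gbol:strand gbol:ReverseStrandPosition .

gbol:ExactPosition_10
    a gbol:ExactPosition ;
    gbol:position "500"^^xsd:integer .

gbol:ExactPosition_11
    a gbol:ExactPosition ;
    gbol:position "800"^^xsd:integer .

gbol:ProvenanceAnnotation_12
    a gbol:ProvenanceAnnotation ;
    gbol:experiment <http://purl.obolibrary.org/obo/ECO_0000203> .

gbol:FeatureProvenance_13
    a gbol:FeatureProvenance ;
    gbol:onProperty gbol:featureType ;
    gbol:annotation gbol:ProvenanceAnnotation_12 ;
    gbol:origin gbol:AutomaticAnnotationActivity_1 .

gbol:Feature_14
    a gbol:Feature ;
    gbol:locus "TOY_0003" ;
    gbol:featureType "tRNA" ;
    gbol:location gbol:OrderedCollectionOfRegions_15 ;
    gbol:provenance gbol:FeatureProvenance_23 .

gbol:OrderedCollectionOfRegions_15
    a gbol:OrderedCollectionOfRegions ;
    gbol:reference gbol:chr1 ;
    gbol:memberRegions _:l1 .

_:l1
    rdf:first gbol:Region_16 ;
    rdf:rest _:l2 .

_:l2
    rdf:first gbol:Region_19 ;
    rdf:rest rdf:nil .

gbol:Region_16
    a gbol:Region ;
    gbol:reference gbol:chr1 ;
    gbol:begin gbol:ExactPosition_17 ;
    gbol:end gbol:ExactPosition_18 .

gbol:ExactPosition_17
    a gbol:ExactPosition ;
    gbol:position "900"^^xsd:integer .

gbol:ExactPosition_18
    a gbol:ExactPosition ;
    gbol:position "950"^^xsd:integer .

gbol:Region_19
    a gbol:Region ;
    gbol:reference gbol:chr1 ;
    gbol:begin gbol:ExactPosition_20 ;
    gbol:end gbol:ExactPosition_21 .

gbol:ExactPosition_20
    a gbol:ExactPosition ;
    gbol:position "960"^^xsd:integer .

gbol:ExactPosition_21
    a gbol:ExactPosition ;
    gbol:position "1000"^^xsd:integer .

gbol:ProvenanceAnnotation_22
    a gbol:ProvenanceAnnotation ;
    gbol:experiment <http://purl.obolibrary.org/obo/ECO_0000203> .

gbol:FeatureProvenance_23
    a gbol:FeatureProvenance ;
    gbol:onProperty gbol:featureType ;
    gbol:annotation gbol:ProvenanceAnnotation_22 ;
    gbol:origin gbol:AutomaticAnnotationActivity_1 .

gbol:Document_24
    a gbol:Document ;
    gbol:sequence gbol:chr1 .

gbol:GBOLDataSet_25
    a gbol:GBOLDataSet ;
    gbol:name "toy genome annotation" ;
    gbol:document gbol:Document_24 ;
    gbol:activity gbol:AutomaticAnnotationActivity_1 .

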