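@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix skos: <http://www.w3.org/2004/02/skos/core#> .
@prefix gbol: <http://gbol.life/0.1/> .
@prefix faldo: <http://biohackathon.org/resource/faldo#> .

gbol:
    a owl:Ontology .

gbol:EnumeratedValue
    a owl:Class .

gbol:AfterPosition
    a owl:Class ;
    rdfs:subClassOf gbol:FuzzyPosition ;
    rdfs:label "AfterPosition" ;
    skos:description "A coordinate known to lie after a given base." ;
    skos:exactMatch faldo:AfterPosition ;
    gbol:propertyDefinitions """# the coordinate the true position lies after
position xsd:integer 1..1""" .

gbol:BaseLocation
    a owl:Class ;
    rdfs:subClassOf gbol:Location ;
    rdfs:label "BaseLocation" ;
    skos:description "A single base at a given position." ;
    gbol:propertyDefinitions """# the single base
at Position 1..1
# strand the location lies on
strand @StrandPosition 0..1""" .

gbol:BeforePosition
    a owl:Class ;
    rdfs:subClassOf gbol:FuzzyPosition ;
    rdfs:label "BeforePosition" ;
    skos:description "A coordinate known to lie before a given base." ;
    skos:exactMatch faldo:BeforePosition ;
    gbol:propertyDefinitions """# the coordinate the true position lies before
position xsd:integer 1..1""" .

gbol:CollectionOfRegions
    a owl:Class ;
    rdfs:subClassOf gbol:Location ;
    rdfs:label "CollectionOfRegions" ;
    skos:description "A location made of several regions, possibly on different sequences." ;
    skos:exactMatch faldo:CollectionOfRegions .

gbol:ExactPosition
    a owl:Class ;
    rdfs:subClassOf gbol:Position ;
    rdfs:label "ExactPosition" ;
    skos:description "An exactly known coordinate." ;
    skos:exactMatch faldo:ExactPosition ;
    gbol:propertyDefinitions """# the exactly known coordinate
position xsd:integer 1..1""" .

gbol:FuzzyPosition
    a owl:Class ;
    rdfs:subClassOf gbol:Position ;
    rdfs:label "FuzzyPosition" ;
    skos:description "A coordinate that is not exactly known; subclasses hold plain integers, never nested position objects." ;
    skos:exactMatch faldo:FuzzyPosition .

gbol:InBetweenLocation
    a owl:Class ;
    rdfs:subClassOf gbol:Location ;
    rdfs:label "InBetweenLocation" ;
    skos:description "A site between two adjacent bases, identified by the preceding base." ;
    skos:exactMatch faldo:InBetweenPosition ;
    gbol:propertyDefinitions """# the base after which the in-between site lies
after Position 1..1
# strand the location lies on
strand @StrandPosition 0..1""" .

gbol:InRangePosition
    a owl:Class ;
    rdfs:subClassOf gbol:FuzzyPosition ;
    rdfs:label "InRangePosition" ;
    skos:description "A coordinate known to lie within a closed range." ;
    skos:exactMatch faldo:InRangePosition ;
    gbol:propertyDefinitions """# lowest possible coordinate
beginPosition xsd:integer 1..1
# highest possible coordinate
endPosition xsd:integer 1..1""" .

gbol:Location
    a owl:Class ;
    rdfs:label "Location" ;
    skos:description "An extent on a sequence; the reference lives here, not on the positions, so a location may span sequences." ;
    gbol:propertyDefinitions """# sequence the location is defined on
reference Sequence 0..1""" .

gbol:NumberedCollectionOfRegions
    a owl:Class ;
    rdfs:subClassOf gbol:CollectionOfRegions ;
    rdfs:label "NumberedCollectionOfRegions" ;
    skos:description "Region collection whose members carry explicit numbers." ;
    gbol:propertyDefinitions """# member regions with explicit numbering
numberedRegions Region ~1..N""" .

gbol:OneOfPosition
    a owl:Class ;
    rdfs:subClassOf gbol:FuzzyPosition ;
    rdfs:label "OneOfPosition" ;
    skos:description "A coordinate known to be one of several candidates." ;
    skos:exactMatch faldo:OneOfPosition ;
    gbol:propertyDefinitions """# the candidate coordinates
position xsd:integer 1..N""" .

gbol:OrderedCollectionOfRegions
    a owl:Class ;
    rdfs:subClassOf gbol:CollectionOfRegions ;
    rdfs:label "OrderedCollectionOfRegions" ;
    skos:description "Region collection whose member order is meaningful (a GenBank join)." ;
    gbol:propertyDefinitions """# member regions in biological order
memberRegions Region =1..N""" .

gbol:Position
    a owl:Class ;
    rdfs:label "Position" ;
    skos:description "A single coordinate on a sequence (1-based)." ;
    skos:exactMatch faldo:Position .

gbol:Region
    a owl:Class ;
    rdfs:subClassOf gbol:Location ;
    rdfs:label "Region" ;
    skos:description "A contiguous stretch with begin and end positions." ;
    gbol:ddbjLabel "location" ;
    skos:exactMatch faldo:Region ;
    gbol:propertyDefinitions """# first base of the region
begin Position 1..1
# last base of the region
end Position 1..1
# strand the location lies on
strand @StrandPosition 0..1""" .

gbol:Sequence
    a owl:Class ;
    rdfs:label "Sequence" ;
    skos:description "A biological sequence a location can refer to." .

gbol:UnorderedCollectionOfRegions
    a owl:Class ;
    rdfs:subClassOf gbol:CollectionOfRegions ;
    rdfs:label "UnorderedCollectionOfRegions" ;
    skos:description "Region collection without ordering (a GenBank order)." ;
    gbol:propertyDefinitions """# member regions, unordered
members Region 1..N""" .

gbol:StrandPosition
    a owl:Class ;
    rdfs:subClassOf gbol:EnumeratedValue ;
    rdfs:label "StrandPosition" ;
    skos:description "Strand on which a location lies: forward, reverse or both." ;
    gbol:usageComment "No strand may be given when the referenced sequence is single-stranded or a protein." ;
    skos:exactMatch faldo:BothStrandsPosition, faldo:ForwardStrandPosition, faldo:ReverseStrandPosition .

gbol:ForwardStrandPosition
    a owl:Class ;
    rdfs:subClassOf gbol:StrandPosition .

gbol:ReverseStrandPosition
    a owl:Class ;
    rdfs:subClassOf gbol:StrandPosition .

gbol:BothStrandsPosition
    a owl:Class ;
    rdfs:subClassOf gbol:StrandPosition .

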