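{
  "classes": ["Sequence", "Location", "Region", "BaseLocation", "InBetweenLocation", "CollectionOfRegions", "OrderedCollectionOfRegions", "NumberedCollectionOfRegions", "UnorderedCollectionOfRegions", "Position", "ExactPosition", "FuzzyPosition", "BeforePosition", "AfterPosition", "InRangePosition", "OneOfPosition"],
  "properties": ["Location.reference", "Region.begin", "Region.end", "Region.strand", "BaseLocation.at", "BaseLocation.strand", "InBetweenLocation.after", "InBetweenLocation.strand", "OrderedCollectionOfRegions.memberRegions", "NumberedCollectionOfRegions.numberedRegions", "UnorderedCollectionOfRegions.members", "ExactPosition.position", "BeforePosition.position", "AfterPosition.position", "InRangePosition.beginPosition", "InRangePosition.endPosition", "OneOfPosition.position"],
  "value_sets": "StrandPosition",
  "stats": {
    "classes": 16,
    "properties": 17,
    "value_sets": 1
  }
}
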