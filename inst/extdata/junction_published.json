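{
  "description": "Published MutaMouse integration architecture (structure only; base content is synthetic)",
  "hostChrom": "chr3",
  "deletion": {"start": 37971249, "end": 38436675, "lengthConvention": "difference", "lengthBp": 465426},
  "inversion": {"start": 38436306, "end": 38436675, "lengthConvention": "inclusive", "lengthBp": 370},
  "insertedBasesCount": 4,
  "microhomologyDownstreamBp": 2,
  "monomerLengthBp": 47588,
  "arrayCopyNumber": 29,
  "constitutionalVariantSites": 18
}
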