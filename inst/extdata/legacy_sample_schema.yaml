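id: https://example.org/legacy-sample-schema
name: legacy_sample_schema
title: Legacy Sample Schema (pre-migration)
description: >-
  The source model before migration: position is a single fused string and
  the environment slot carries the legacy name environment_type.
default_range: string
enums:
  EnvironmentTypeEnum:
    description: The broad type of environment a sample was collected from.
    permissible_values:
      soil:
        meaning: ENVO:00001998
      water:
        meaning: ENVO:00002006
      air:
        meaning: ENVO:00002005
      sediment:
        meaning: ENVO:00002007
      sand:
        meaning: ENVO:01000017
classes:
  Sample:
    description: A material sample collected from an environment for analysis.
    attributes:
      id:
        description: Unique persistent CURIE identifier of the sample.
        identifier: true
        range: uriorcurie
      position:
        description: Fused "latitude, longitude" string.
        range: string
        required: true
      environment_type:
        description: The type of environment the sample was collected from.
        range: EnvironmentTypeEnum
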