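id: https://example.org/sample-schema
name: sample_schema
title: Microbiome Sample Schema
license: https://creativecommons.org/publicdomain/zero/1.0/
description: >-
  Metadata schema for environmental microbiome samples. Positions are split
  into decimal-degree latitude and longitude, depths are recorded in metres,
  and environment types are constrained to an ENVO-mapped controlled
  vocabulary. All prefix bases here (including the MIXS base) are fixture
  constants of this package.
prefixes:
  ex: https://example.org/sample-schema/
  schema: http://schema.org/
  OBI: http://purl.obolibrary.org/obo/OBI_
  ENVO: http://purl.obolibrary.org/obo/ENVO_
  MIXS: https://w3id.org/mixs/
default_range: string
enums:
  EnvironmentTypeEnum:
    description: The broad type of environment a sample was collected from.
    permissible_values:
      soil:
        description: Terrestrial soil.
        meaning: ENVO:00001998
      water:
        description: An aquatic environment.
        meaning: ENVO:00002006
      air:
        description: The atmosphere.
        meaning: ENVO:00002005
      sediment:
        description: Particulate matter deposited under water.
        meaning: ENVO:00002007
      sand:
        description: Granular sand.
        meaning: ENVO:01000017
classes:
  Sample:
    description: A material sample collected from an environment for analysis.
    class_uri: OBI:0000747
    attributes:
      id:
        description: Unique persistent CURIE identifier of the sample.
        identifier: true
        range: uriorcurie
      latitude:
        description: Latitude of the sampling location in decimal degrees.
        range: float
        required: true
        slot_uri: schema:latitude
      longitude:
        description: Longitude of the sampling location in decimal degrees.
        range: float
        required: true
        slot_uri: schema:longitude
      depth:
        description: Sampling depth below the local surface, in metres.
        range: float
        unit: m
        slot_uri: MIXS:0000018
      environment_type:
        description: The type of environment the sample was collected from.
        range: EnvironmentTypeEnum
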