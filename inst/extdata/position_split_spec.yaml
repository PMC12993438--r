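# Migration spec: split the fused "position" field into latitude and
# longitude, and relabel environment_type to the target project's
# terminology.
- split:
    class: Sample
    source_slot: position
    targets: [latitude, longitude]
    delimiter: ","
    target_ranges: [float, float]
- rename:
    class: Sample
    old_slot: environment_type
    new_slot: sample_type
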