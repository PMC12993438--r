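record	field	multiplicity	required	range	parents	desc
> class	slot	cardinality	required	range	is_a	description
>						
Sample						
Sample	latitude	0‥1	TRUE	float		The latitude of the sample location.
Sample	longitude	0‥1	TRUE	float		The longitude of the sample location.
Sample	environment_type	0…1		EnvironmentTypeEnum		The environment from which the sample was taken.
Study	id	1	TRUE	uriorcurie		The unique identifier of a study.
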