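screen	hairpin_id	fold_change
PLX	94	0.46
PLX	96	0.42
PLX	159	0.52
PLX	161	0.54
SCH	94	0.62
SCH	159	0.6
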