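# Example scenario configuration: continuous division in rich medium.
# One key = value per line; "scenario" selects a preset, other keys
# override individual model parameters.
scenario = rich_nutrient
a0 = 0.01
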