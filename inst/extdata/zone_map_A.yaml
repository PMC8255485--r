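group: A
arm_length: 60.0
arm_width: 14.0
neutral_radius: 18.0
reward_depth: 20.0
sandpaper_depth: 17.0
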